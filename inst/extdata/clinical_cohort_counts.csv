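cohort,level,stratum,tp,fp,fn,tn
cross_validation,per_video,all,443,36,49,702
cross_validation,per_study,all,87,7,6,105
testing,per_video,all,276,45,30,477
testing,per_study,all,57,4,5,72
cross_validation,per_video,lvef_40_60,131,23,37,91
cross_validation,per_study,lvef_40_60,33,5,4,5
testing,per_video,lvef_40_60,126,23,26,71
testing,per_study,lvef_40_60,32,3,1,5
testing,per_study,expert1,37,5,4,54
testing,per_study,expert2,33,9,4,54
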