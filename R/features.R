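#' Frame feature extractor specification
#'
#' The classifier consumes 2048-length per-frame feature vectors.  Two
#' backends share that contract: `projection_stub` (default) downsamples the
#' frame to 32 x 32 and applies a fixed, seeded Gaussian random linear
#' projection to 2048 dimensions - deterministic, dependency-free and
#' suitable for offline training and testing; `pretrained_cnn` designates the
#' penultimate 2048-wide pooled layer of an ImageNet-pretrained Inception-v3
#' and requires externally supplied weights, which this package does not
#' bundle - selecting it without a weights file is an error.
#'
#' @param backend `"projection_stub"` or `"pretrained_cnn"`.
#' @param seed integer; fixes the stub's projection matrix.
#' @param pool_size side length of the downsampled frame fed to the stub.
#' @return object of class `extractor_spec`.
#' @export
extractor_spec <- function(backend = c("projection_stub", "pretrained_cnn"),
                           seed = 7L, pool_size = 32L) {
  backend <- match.arg(backend)
  structure(list(backend = backend, seed = as.integer(seed),
                 pool_size = as.integer(pool_size), n_features = 2048L),
            class = "extractor_spec")
}

.proj_cache <- new.env(parent = emptyenv())

.stub_projection <- function(spec) {
  key <- paste0("w", spec$seed, "_", spec$pool_size)
  if (is.null(.proj_cache[[key]])) {
    d <- spec$pool_size^2
    .proj_cache[[key]] <- withr::with_seed(spec$seed,
      matrix(stats::rnorm(spec$n_features * d, sd = 1 / sqrt(d)),
             spec$n_features, d))
  }
  .proj_cache[[key]]
}

#' Extract a 2048-length feature vector from one frame
#'
#' @param frame numeric matrix, 299 x 299 (grayscale in \[0,1\]).
#' @param spec an [extractor_spec()].
#' @return numeric vector of length 2048.
#' @export
extract_frame_features <- function(frame, spec = extractor_spec()) {
  if (!is.matrix(frame) || nrow(frame) != 299L || ncol(frame) != 299L)
    stop("frame must be a 299 x 299 matrix")
  if (spec$backend == "pretrained_cnn")
    stop("pretrained_cnn backend requires externally supplied Inception-v3 ",
         "weights; none are bundled. Use the projection_stub backend.")
  pooled <- resample_image(frame, spec$pool_size)
  as.numeric(.stub_projection(spec) %*% as.numeric(pooled))
}

#' Assemble the (4, 2048) feature matrix for one video
#'
#' Row i holds the features of frame i, frames in temporal order
#' (ED, systolic, systolic, ES).
#'
#' @param frames list of exactly 4 frames (299 x 299 matrices), e.g. from
#'   [select_input_frames()].
#' @param spec an [extractor_spec()].
#' @return 4 x 2048 numeric matrix of class `feature_matrix`.
#' @export
assemble_feature_matrix <- function(frames, spec = extractor_spec()) {
  if (length(frames) != 4L)
    stop("expected exactly 4 frames, got ", length(frames))
  m <- t(vapply(frames, extract_frame_features, numeric(2048L), spec = spec))
  if (!all(is.finite(m))) stop("non-finite feature values")
  structure(m, class = c("feature_matrix", class(m)))
}
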