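#' Normalize stack intensities to the unit interval
#'
#' Affinely rescales intensities to \[0,1\]: `(x - min) / (max - min)`.
#' A constant stack carries no topological signal; it is mapped to all
#' zeros with a warning. Idempotent on stacks already spanning \[0,1\].
#'
#' @param stack An [intensity_stack()] (or bare array, coerced).
#' @return The normalized `intensity_stack`; shape and axes unchanged.
#' @examples
#' s <- intensity_stack(matrix(c(0, 128, 255), 1, 3))
#' normalize_intensity(s)$data
#' @export
normalize_intensity <- function(stack) {
  stack <- as_stack(stack)
  x <- stack$data
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    warning("constant stack: nothing to segment; returning all zeros")
    stack$data <- array(0, dim = dim(x))
    return(stack)
  }
  stack$data <- (x - lo) / (hi - lo)
  stack
}

#' Gaussian denoising over the spatial axes
#'
#' Smooths the stack with an isotropic Gaussian kernel of standard
#' deviation `sigma` (in voxel units) using separable 1-D convolutions
#' with mirror boundary handling. For videos only the lateral (y,x)
#' axes are smoothed: frames never bleed into each other. `sigma = 0`
#' is the identity.
#'
#' @param stack An [intensity_stack()].
#' @param sigma Non-negative standard deviation in voxels.
#' @return The smoothed stack, same shape and axes.
#' @export
gaussian_denoise <- function(stack, sigma) {
  stack <- as_stack(stack)
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  if (sigma == 0) return(stack)
  d <- dim(stack$data)
  sigmas <- rep(0, length(d))
  sigmas[spatial_axes_for(stack$axes)] <- sigma
  out <- cpp_gaussian_blur(as.numeric(stack$data), as.integer(d), sigmas)
  stack$data <- array(out, dim = d)
  stack
}

#' Contrast sweep: discard the dimmest background voxels
#'
#' Sets to zero every voxel whose intensity falls at or below the given
#' empirical quantile of the whole stack's intensity distribution
#' (default: the lowest 5%). This suppresses dim background before
#' segmentation and, on well-contrasted images, substantially reduces
#' the number of candidate components. `quantile = 0` leaves the stack
#' untouched.
#'
#' @param stack An [intensity_stack()].
#' @param quantile Quantile in \[0, 1) below which voxels are zeroed.
#' @return The filtered stack; no voxel's intensity ever increases.
#' @export
contrast_sweep <- function(stack, quantile = 0.05) {
  stack <- as_stack(stack)
  if (!is.numeric(quantile) || length(quantile) != 1 || is.na(quantile) ||
      quantile < 0 || quantile >= 1)
    stop("`quantile` must be a single number in [0, 1)")
  if (quantile == 0) return(stack)
  x <- stack$data
  thr <- stats::quantile(x, probs = quantile, names = FALSE)
  x[x <= thr] <- 0
  stack$data <- x
  stack
}
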