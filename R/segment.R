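#' Segmentation configuration
#'
#' Bundles the two knobs of the persistence segmenter. `tau` is the
#' persistence threshold on the normalized intensity scale: it gates
#' how far below its root a voxel may sit and still be attached
#' (`root - I(v) <= tau`), how different two roots may be and still
#' merge, and the minimum root intensity a component needs to survive
#' background filtering. `connectivity` selects the voxel neighbourhood:
#' `"full"` (8 neighbours in 2-D / 26 in 3-D, the default — blurred
#' objects stay connected across diagonals) or `"faces"` (4 / 6).
#'
#' @param tau Persistence threshold in \[0,1\].
#' @param connectivity `"full"` or `"faces"`.
#' @return A `seg_config` object.
#' @examples
#' seg_config(tau = 0.4, connectivity = "faces")
#' @export
seg_config <- function(tau = 0.5, connectivity = c("full", "faces")) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0 || tau > 1)
    stop("`tau` must be a single number in [0, 1]")
  connectivity <- match.arg(connectivity)
  structure(list(tau = tau, connectivity = connectivity),
            class = "seg_config")
}

#' Filtration order of a stack
#'
#' Returns the superlevel-set filtration: a deterministic total order of
#' all voxels by decreasing intensity, ties broken lexicographically by
#' coordinate (first array axis most significant). The sweep in
#' [segment_stack()] visits voxels in exactly this order.
#'
#' @param stack An [intensity_stack()] with values in \[0,1\].
#' @return A list with `order` (matrix of 1-based voxel coordinates,
#'   one row per voxel, in filtration order) and `intensity` (the
#'   matching non-increasing intensities).
#' @export
build_filtration <- function(stack) {
  stack <- as_stack(stack)
  d <- dim(stack$data)
  ord <- cpp_filtration_order(as.numeric(stack$data), as.integer(d))
  coords <- arrayInd(ord, d)
  colnames(coords) <- axis_names_for(stack$axes)
  list(order = coords, intensity = as.numeric(stack$data)[ord])
}

#' Topological segmentation of a frame or volume
#'
#' Segments an image or z-stack into connected components by persistent
#' homology over the cubical complex of its voxel grid. Voxels are swept
#' in filtration order (decreasing intensity); each local maximum seeds
#' a component rooted at its brightest voxel, dimmer voxels attach to
#' the brightest neighbouring component when their intensity is within
#' `tau` of that component's root, components whose roots differ by at
#' most `tau` merge when they meet, and components rooted dimmer than
#' `tau` are discarded as background. The same sweep serves 2-D frames
#' and 3-D volumes (any axis count, in fact); only the neighbourhood
#' changes.
#'
#' @param stack An [intensity_stack()] normalized to \[0,1\]
#'   (see [normalize_intensity()]).
#' @param config A [seg_config()].
#' @return A `ph_segmentation`: list with `labels` (integer array, same
#'   shape as the input; 0 = background, k >= 1 = component k, ids
#'   ordered by decreasing root intensity with lexicographic
#'   tie-breaks), `components` (data frame: `id`, root coordinates,
#'   `root_intensity`, `size`), `config` and `axes`.
#' @examples
#' s <- intensity_stack(matrix(c(1, 0.6, 0.9), 1, 3))
#' segment_stack(s, seg_config(tau = 0.5))$components
#' @export
segment_stack <- function(stack, config = seg_config()) {
  stack <- as_stack(stack)
  if (!inherits(config, "seg_config")) stop("`config` must be a seg_config")
  x <- stack$data
  if (length(x) == 0) stop("empty stack")
  if (min(x) < 0 || max(x) > 1)
    stop("intensities outside [0,1]; run normalize_intensity() first")
  d <- dim(x)
  res <- cpp_segment(as.numeric(x), as.integer(d), config$tau,
                     config$connectivity == "full")
  labels <- array(res$labels, dim = d)
  K <- length(res$root_index)
  coords <- arrayInd(res$root_index, d)
  colnames(coords) <- paste0("root_", axis_names_for(stack$axes))
  components <- data.frame(id = seq_len(K))
  if (K > 0) components <- cbind(components, as.data.frame(coords))
  else for (nm in paste0("root_", axis_names_for(stack$axes)))
    components[[nm]] <- integer(0)
  components$root_intensity <- as.numeric(res$root_intensity)
  components$size <- as.integer(res$size)
  structure(list(labels = labels, components = components,
                 config = config, axes = stack$axes,
                 voxel_size = stack$voxel_size),
            class = "ph_segmentation")
}

#' @export
print.ph_segmentation <- function(x, ...) {
  cat(sprintf("<ph_segmentation> %s %s: %d component(s), tau = %g, %s\n",
              x$axes, paste(dim(x$labels), collapse = "x"),
              nrow(x$components), x$config$tau, x$config$connectivity))
  invisible(x)
}

#' Number of components in a segmentation
#' @param result A `ph_segmentation`.
#' @return Integer component count.
#' @export
n_components <- function(result) nrow(result$components)

#' Calibrate the persistence threshold against an expected count
#'
#' The component count is non-increasing in `tau`, so the threshold can
#' be searched monotonely. Starting from `tau = 0.5`, the search
#' bisects on (0, 1\] until the segmentation returns exactly
#' `expected_count` components, the grid resolution `tol` is reached,
#' or `max_iters` segmentations have been run. If no visited threshold
#' achieves the expected count, the closest one is returned (ties
#' resolved towards the smaller count) with a warning.
#'
#' @param stack A normalized [intensity_stack()].
#' @param expected_count Positive integer: the known/expected number of
#'   biological structures.
#' @param config A [seg_config()]; its `tau` is ignored (the search
#'   supplies it), its connectivity is used.
#' @param max_iters Maximum number of segmentations to run.
#' @param tol Threshold grid resolution.
#' @return List with `tau` (the calibrated threshold) and `result`
#'   (its `ph_segmentation`).
#' @export
calibrate_tau <- function(stack, expected_count, config = seg_config(),
                          max_iters = 50, tol = 1e-3) {
  stack <- as_stack(stack)
  if (!is.numeric(expected_count) || length(expected_count) != 1 ||
      expected_count < 1 || expected_count != round(expected_count))
    stop("`expected_count` must be a positive integer")
  run <- function(tau) segment_stack(stack, seg_config(tau, config$connectivity))

  best <- NULL
  note <- function(tau, res) {
    k <- n_components(res)
    dk <- abs(k - expected_count)
    if (is.null(best) || dk < best$dk || (dk == best$dk && k < best$k))
      best <<- list(tau = tau, result = res, k = k, dk = dk)
    k
  }

  tau <- 0.5
  res <- run(tau)
  k <- note(tau, res)
  if (k == expected_count) return(list(tau = tau, result = res))

  # more components than expected -> need a larger tau, and vice versa
  if (k > expected_count) { lo <- 0.5; hi <- 1 } else { lo <- 0; hi <- 0.5 }
  iters <- 1
  while (iters < max_iters && (hi - lo) > tol) {
    tau <- (lo + hi) / 2
    res <- run(tau)
    k <- note(tau, res)
    iters <- iters + 1
    if (k == expected_count) return(list(tau = tau, result = res))
    if (k > expected_count) lo <- tau else hi <- tau
  }
  warning(sprintf(
    "no threshold on the search grid yields %d component(s); returning tau = %g with %d",
    expected_count, best$tau, best$k))
  list(tau = best$tau, result = best$result)
}
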