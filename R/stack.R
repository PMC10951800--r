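#' Grayscale image stack with axis semantics
#'
#' An `intensity_stack` wraps an n-D numeric array of fluorescence
#' intensities together with a tag saying how its axes should be read:
#' a single 2D frame (`frame2d`, axes y,x), a volumetric z-stack
#' (`volume`, axes z,y,x) or a time-lapse video (`video`, axes t,y,x).
#' Intensities are dimensionless; segmentation requires them to lie in
#' \[0,1\] (see [normalize_intensity()]).
#'
#' @param data Numeric matrix (frame) or 3-D array (volume/video).
#' @param axes One of `"frame2d"`, `"volume"`, `"video"`. Defaults to
#'   `"frame2d"` for matrices and `"volume"` for 3-D arrays.
#' @param voxel_size Optional numeric vector of physical voxel edge
#'   lengths in micrometres, one per spatial axis (e.g. `c(z = 0.54,
#'   y = 0.62, x = 0.62)` for a confocal stack). Used only to report
#'   physical-unit statistics; never used by the segmenter itself.
#'
#' @return An object of class `intensity_stack` with elements `data`,
#'   `axes` and `voxel_size`.
#' @examples
#' img <- matrix(0, 16, 16)
#' img[5:8, 5:8] <- 1
#' intensity_stack(img, "frame2d")
#' @export
intensity_stack <- function(data, axes = NULL, voxel_size = NULL) {
  if (is.matrix(data)) data <- array(data, dim = dim(data))
  if (!is.array(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix or array")
  nd <- length(dim(data))
  if (is.null(axes)) axes <- if (nd == 2) "frame2d" else "volume"
  axes <- match.arg(axes, c("frame2d", "volume", "video"))
  if (axes == "frame2d" && nd != 2)
    stop("frame2d stacks must be 2-D (y,x)")
  if (axes %in% c("volume", "video") && nd != 3)
    stop(sprintf("%s stacks must be 3-D", axes))
  if (any(!is.finite(data))) stop("intensities must be finite")
  if (!is.null(voxel_size)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != length(spatial_axes_for(axes)) ||
        any(voxel_size <= 0))
      stop("`voxel_size` must give a positive size per spatial axis")
  }
  structure(list(data = data, axes = axes, voxel_size = voxel_size),
            class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  cat(sprintf("<intensity_stack> %s %s, range [%.4g, %.4g]\n",
              x$axes, paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  if (!is.null(x$voxel_size))
    cat("  voxel size (um): ", paste(x$voxel_size, collapse = " x "), "\n")
  invisible(x)
}

#' @export
dim.intensity_stack <- function(x) dim(x$data)

axis_names_for <- function(axes) {
  switch(axes,
         frame2d = c("y", "x"),
         volume = c("z", "y", "x"),
         video = c("t", "y", "x"))
}

spatial_axes_for <- function(axes) {
  switch(axes, frame2d = 1:2, volume = 1:3, video = 2:3)
}

as_stack <- function(x, axes = NULL, voxel_size = NULL) {
  if (inherits(x, "intensity_stack")) return(x)
  intensity_stack(x, axes = axes, voxel_size = voxel_size)
}

# Extract frame t of a video as a frame2d stack (shares voxel_size for y,x).
video_frame <- function(stack, t) {
  stopifnot(stack$axes == "video")
  vs <- stack$voxel_size
  intensity_stack(stack$data[t, , , drop = TRUE], "frame2d",
                  voxel_size = if (!is.null(vs)) vs[2:3])
}
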