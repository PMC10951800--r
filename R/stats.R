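#' Per-component descriptive statistics
#'
#' For every segmented component: centroid and spread (population
#' standard deviation of member voxel coordinates, so a singleton has
#' spread 0) per axis, minimum / mean / maximum intensity, and volume
#' as a voxel count — converted to cubic micrometres when the stack
#' carries a `voxel_size`. The centroid is unweighted by default; set
#' `weighted = TRUE` for an intensity-weighted centroid.
#'
#' @param result A `ph_segmentation` produced from `stack`.
#' @param stack The [intensity_stack()] that was segmented.
#' @param weighted Intensity-weight the centroid? Default `FALSE`.
#' @return Data frame, one row per component: `id`, `centroid_*`,
#'   `sd_*` (axis-named columns), `min_intensity`, `mean_intensity`,
#'   `max_intensity`, `volume_vox` and (given a voxel size)
#'   `volume_um3`.
#' @export
component_stats <- function(result, stack, weighted = FALSE) {
  stack <- as_stack(stack)
  if (!inherits(result, "ph_segmentation")) stop("`result` must be a ph_segmentation")
  if (!identical(dim(result$labels), dim(stack$data)))
    stop("shape mismatch between segmentation and stack")
  ax <- axis_names_for(stack$axes)
  labs <- result$labels
  x <- stack$data
  K <- nrow(result$components)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    id <- result$components$id[k]
    idx <- which(labs == id)
    coords <- arrayInd(idx, dim(labs))
    ints <- x[idx]
    w <- if (weighted) ints / sum(ints) else rep(1 / length(idx), length(idx))
    centroid <- colSums(coords * w)
    spread <- sqrt(colMeans(coords^2) - colMeans(coords)^2)
    spread[spread < 0 | !is.finite(spread)] <- 0
    row <- data.frame(id = id)
    for (a in seq_along(ax)) row[[paste0("centroid_", ax[a])]] <- centroid[a]
    for (a in seq_along(ax)) row[[paste0("sd_", ax[a])]] <- spread[a]
    row$min_intensity <- min(ints)
    row$mean_intensity <- mean(ints)
    row$max_intensity <- max(ints)
    row$volume_vox <- length(idx)
    if (!is.null(stack$voxel_size))
      row$volume_um3 <- length(idx) * prod(stack$voxel_size)
    rows[[k]] <- row
  }
  if (K == 0) {
    out <- data.frame(id = integer(0))
    for (a in ax) out[[paste0("centroid_", a)]] <- numeric(0)
    for (a in ax) out[[paste0("sd_", a)]] <- numeric(0)
    out$min_intensity <- numeric(0)
    out$mean_intensity <- numeric(0)
    out$max_intensity <- numeric(0)
    out$volume_vox <- integer(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Per-track statistics, lifespans and the component-count series
#'
#' Produces the temporal summaries: per-frame spatial statistics of
#' each track's component, a one-row-per-track lifespan table (birth,
#' death, duration, cause, parent), and the number of live objects per
#' frame ("change in identified objects over time").
#'
#' @param tracks A `ph_tracks` produced from `video`.
#' @param video The video [intensity_stack()] that was tracked.
#' @return List with data frames `per_frame`, `lifespan` and `counts`.
#' @export
track_stats <- function(tracks, video) {
  video <- as_stack(video)
  if (!inherits(tracks, "ph_tracks")) stop("`tracks` must be a ph_tracks")
  nT <- length(tracks$frame_results)
  if (dim(video$data)[1] != nT)
    stop("shape mismatch between tracks and video")

  per_frame <- list()
  for (t in seq_len(nT)) {
    asg <- tracks$assignment[tracks$assignment$frame == t, ]
    if (nrow(asg) == 0) next
    st <- component_stats(tracks$frame_results[[t]], video_frame(video, t))
    st <- merge(asg, st, by.x = "comp_id", by.y = "id")
    per_frame[[t]] <- st[order(st$track_id), ]
  }
  per_frame <- if (length(per_frame)) do.call(rbind, per_frame)
               else data.frame(comp_id = integer(0), frame = integer(0),
                               track_id = integer(0))
  rownames(per_frame) <- NULL

  lifespan <- tracks$tracks[, c("id", "parent_id", "birth_frame",
                                "death_frame", "death_cause",
                                "st_root_intensity")]
  lifespan$duration <- lifespan$death_frame - lifespan$birth_frame + 1L

  counts <- data.frame(
    frame = seq_len(nT),
    n_components = vapply(seq_len(nT), function(t)
      sum(tracks$assignment$frame == t), integer(1)))

  list(per_frame = per_frame, lifespan = lifespan, counts = counts)
}

#' Sphere-equivalent diameter from a volume
#'
#' Convenience inversion of the sphere volume formula,
#' d = (6V/pi)^(1/3): the diameter a component would have were it a
#' perfect sphere of the same volume. Reported alongside cell volumes
#' when a rough length scale is wanted.
#'
#' @param volume Volume(s), e.g. in cubic micrometres.
#' @return Diameter(s) in the corresponding length unit.
#' @examples
#' sphere_equiv_diameter(1961.6) # ~15.5 um for a typical T cell
#' @export
sphere_equiv_diameter <- function(volume) (6 * volume / pi)^(1 / 3)
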