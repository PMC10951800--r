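#' Read an image stack from TIFF (or a directory of frames)
#'
#' Reads a multi-page TIFF (8/16/32-bit integer or float) or a
#' directory of per-frame TIFF/PNG images (sorted by filename) into an
#' [intensity_stack()]. Integer pixel values are scaled by their type
#' maximum so intensities land in \[0,1\]; colour pages are collapsed
#' to grayscale by channel averaging (with a warning).
#'
#' @param path A `.tif`/`.tiff` file or a directory of frames.
#' @param axes Axis hint: `"volume"` (z,y,x), `"video"` (t,y,x) or
#'   `"frame2d"`. A single-page file read as video is accepted as a
#'   1-frame video with a warning.
#' @param voxel_size Optional physical voxel size per spatial axis (um).
#' @return An `intensity_stack`.
#' @export
read_stack <- function(path, axes = c("volume", "video", "frame2d"),
                       voxel_size = NULL) {
  axes <- match.arg(axes)
  to_gray <- function(m) {
    if (length(dim(m)) == 3) {
      warning("colour image collapsed to grayscale by channel averaging")
      m <- apply(m, c(1, 2), mean)
    }
    m
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no TIFF/PNG frames found in ", path)
    pages <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) to_gray(png::readPNG(f))
      else to_gray(tiff::readTIFF(f))
    })
  } else {
    if (!file.exists(path)) stop("cannot read ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages) || (is.array(pages) && !is.list(pages)))
      pages <- list(pages)
    pages <- lapply(pages, to_gray)
  }
  shp <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shp)) > 1) stop("inconsistent frame shapes in ", path)
  if (axes == "frame2d") {
    if (length(pages) > 1) stop("frame2d requested but input has multiple pages")
    return(intensity_stack(pages[[1]], "frame2d", voxel_size = voxel_size))
  }
  if (axes == "video" && length(pages) == 1)
    warning("single-page input read as a 1-frame video")
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  intensity_stack(arr, axes, voxel_size = voxel_size)
}

write_label_tiff <- function(labels_by_page, path, max_label) {
  if (max_label > 65535) {
    warning("more than 65535 components: writing 32-bit labels")
    pages <- lapply(labels_by_page, function(m) m / (2^32 - 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    pages <- lapply(labels_by_page, function(m) m / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a label TIFF written by [write_labels()]
#'
#' @param path Label TIFF path.
#' @param bits Bit depth it was written with (16 by default).
#' @return Integer array (pages, y, x), or (y, x) for one page.
#' @export
read_labels <- function(path, bits = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (bits >= 32) 2^32 - 1 else 2^bits - 1
  pages <- lapply(pages, function(m) array(as.integer(round(m * scale)), dim(m)))
  if (length(pages) == 1) return(pages[[1]])
  arr <- array(0L, dim = c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}

#' Write segmentation or tracking results to disk
#'
#' Writes, under `dir`: `labels.tif` (16-bit label map; one page per
#' z-slice for volumes, per frame with stable track ids for videos),
#' `stats.csv` (per-component or per-track-per-frame statistics), and
#' for tracking results `lifespans.csv` plus `lineage.json` (nodes,
#' split edges with frames, merge annotations). Label id 0 is always
#' background. Maps with more than 65535 components switch to 32-bit
#' with a warning.
#'
#' @param result A `ph_segmentation` or `ph_tracks`.
#' @param dir Output directory (created if needed).
#' @param stack The source [intensity_stack()] (for statistics);
#'   optional, statistics are skipped when absent.
#' @return Invisibly, the vector of files written.
#' @export
write_labels <- function(result, dir, stack = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (inherits(result, "ph_segmentation")) {
    lab <- result$labels
    pages <- if (result$axes == "frame2d") list(lab)
             else lapply(seq_len(dim(lab)[1]), function(i) lab[i, , ])
    p <- file.path(dir, "labels.tif")
    write_label_tiff(pages, p, max(0, max(lab)))
    files <- c(files, p)
    if (!is.null(stack)) {
      p <- file.path(dir, "stats.csv")
      utils::write.csv(component_stats(result, stack), p, row.names = FALSE)
      files <- c(files, p)
    }
  } else if (inherits(result, "ph_tracks")) {
    lab <- track_labels(result)
    pages <- lapply(seq_len(dim(lab)[1]), function(i) lab[i, , ])
    p <- file.path(dir, "labels.tif")
    write_label_tiff(pages, p, max(0, max(lab)))
    files <- c(files, p)
    lineage <- list(
      nodes = result$tracks$id,
      tracks = result$tracks,
      split_edges = result$lineage$edges,
      merges = result$lineage$merges)
    p <- file.path(dir, "lineage.json")
    jsonlite::write_json(lineage, p, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
    p <- file.path(dir, "lifespans.csv")
    ls <- result$tracks
    ls$duration <- ls$death_frame - ls$birth_frame + 1L
    utils::write.csv(ls, p, row.names = FALSE)
    files <- c(files, p)
    if (!is.null(stack)) {
      p <- file.path(dir, "stats.csv")
      utils::write.csv(track_stats(result, stack)$per_frame, p,
                       row.names = FALSE)
      files <- c(files, p)
    }
  } else stop("`result` must be a ph_segmentation or ph_tracks")
  invisible(files)
}

write_provenance <- function(dir, params) {
  params$package_version <- as.character(utils::packageVersion("phseg"))
  params$r_version <- R.version.string
  params$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  p <- file.path(dir, "provenance.json")
  jsonlite::write_json(params, p, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(p)
}
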