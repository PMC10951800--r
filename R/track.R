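#' Per-frame 2-D segmentation of a video
#'
#' Runs [segment_stack()] independently on every frame of a t-stack
#' with the same threshold and connectivity. This is the first stage of
#' temporal tracking: it yields the spatial components and their roots
#' per frame, which [link_tracks()] then connects through time.
#'
#' @param video An [intensity_stack()] with `axes = "video"`.
#' @param config A [seg_config()].
#' @return List of `ph_segmentation`, one per frame.
#' @export
segment_frames <- function(video, config = seg_config()) {
  video <- as_stack(video)
  if (video$axes != "video")
    stop("`video` must be an intensity_stack with axes = \"video\"")
  lapply(seq_len(dim(video$data)[1]),
         function(t) segment_stack(video_frame(video, t), config))
}

new_track <- function(id, parent_id, birth, comp) {
  list(id = id, parent_id = parent_id,
       birth_frame = birth, death_frame = NA_integer_,
       death_cause = NA_character_, merged_into = NA_integer_,
       comps = stats::setNames(comp$id, birth),
       st_root_intensity = comp$root_intensity,
       st_root_frame = birth, st_root_y = comp$root_y, st_root_x = comp$root_x)
}

# TRUE when root a = (frame,y,x,intensity) beats b: brighter wins; ties go to
# the lexicographically smaller (frame, y, x).
root_beats <- function(ia, fa, ya, xa, ib, fb, yb, xb) {
  if (ia != ib) return(ia > ib)
  if (fa != fb) return(fa < fb)
  if (ya != yb) return(ya < yb)
  xa < xb
}

#' Link per-frame components into spatiotemporal tracks
#'
#' Builds tracks from consecutive-frame pixel overlap, with split and
#' merge handling. Every frame-1 component founds a track. A live
#' track's component is compared against the components occupying the
#' same pixels in the next frame: no successor and the track dies
#' (`vanished`); one successor and the track continues, its
#' spatiotemporal root updated to the brighter of the running root and
#' the successor's spatial root; two or more successors and the one
#' with the brightest spatial root continues the track while each other
#' successor births a child track (a split, recorded as a lineage
#' edge). If after this a next-frame component is claimed by several
#' tracks, the objects have merged: the claimant with the brightest
#' spatiotemporal root keeps it and the others die (`merged_into:<id>`).
#' Components claimed by nobody found new parentless tracks. Tracks
#' alive at the last frame end with cause `end_of_video`.
#'
#' There is no motion model: objects are linked only when their pixel
#' footprints overlap between consecutive frames, so an object drifting
#' more than its own length per frame will not be followed.
#'
#' @param frame_results List of per-frame `ph_segmentation` (from
#'   [segment_frames()]), all with identical frame shapes.
#' @return A `ph_tracks` object: `tracks` (data frame: `id`,
#'   `parent_id`, `birth_frame`, `death_frame`, `death_cause`,
#'   `merged_into`, spatiotemporal root intensity and location),
#'   `lineage` (split `edges` and `merges` data frames),
#'   `assignment` (frame, component id, track id) and `frame_results`.
#'   Frames are 1-based.
#' @export
link_tracks <- function(frame_results) {
  if (length(frame_results) < 1) stop("need at least one frame")
  shapes <- vapply(frame_results, function(r) paste(dim(r$labels), collapse = "x"), "")
  if (length(unique(shapes)) > 1) stop("inconsistent frame shapes")
  nT <- length(frame_results)

  tracks <- list()
  next_id <- 1L
  edges <- list()   # parent, child, frame (child's birth = split frame)
  merges <- list()  # loser, winner, frame (frame = loser's death frame)
  assignment <- list()

  # live: component id (this frame) -> track id
  live <- integer(0)
  comps0 <- frame_results[[1]]$components
  for (i in seq_len(nrow(comps0))) {
    tracks[[next_id]] <- new_track(next_id, NA_integer_, 1L, comps0[i, ])
    live[as.character(comps0$id[i])] <- next_id
    next_id <- next_id + 1L
  }
  if (nrow(comps0) > 0)
    assignment[[1]] <- data.frame(frame = 1L, comp_id = comps0$id,
                                  track_id = unname(live[as.character(comps0$id)]))

  for (t in seq_len(nT - 1)) {
    lab_a <- frame_results[[t]]$labels
    lab_b <- frame_results[[t + 1]]$labels
    comps_b <- frame_results[[t + 1]]$components
    both <- lab_a > 0 & lab_b > 0
    pairs <- unique(cbind(a = lab_a[both], b = lab_b[both]))

    # claims on next-frame components; children created by splits claim too
    claims <- list()  # comp id (t+1) -> integer vector of track ids
    newborn <- list() # track id -> track (not yet registered)
    succ_root <- list()

    for (ci in names(live)) {
      tr_id <- live[[ci]]
      succ <- sort(pairs[pairs[, "a"] == as.integer(ci), "b"])
      if (length(succ) == 0) {
        tracks[[tr_id]]$death_frame <- t
        tracks[[tr_id]]$death_cause <- "vanished"
        next
      }
      # component ids are ordered by decreasing root intensity with
      # lexicographic tie-breaks, so the smallest id is the brightest root
      cont <- succ[1]
      key <- as.character(cont)
      claims[[key]] <- c(claims[[key]], tr_id)
      if (length(succ) > 1) {
        for (s in succ[-1]) {
          comp <- comps_b[comps_b$id == s, ]
          child <- new_track(next_id, tr_id, t + 1L, comp)
          newborn[[as.character(next_id)]] <- child
          k2 <- as.character(s)
          claims[[k2]] <- c(claims[[k2]], next_id)
          next_id <- next_id + 1L
        }
      }
    }

    get_track <- function(id) {
      k <- as.character(id)
      if (!is.null(newborn[[k]])) newborn[[k]] else tracks[[id]]
    }

    new_live <- integer(0)
    claimed <- rep(FALSE, nrow(comps_b))
    for (key in names(claims)) {
      cid <- as.integer(key)
      comp <- comps_b[comps_b$id == cid, ]
      claimants <- claims[[key]]
      winner <- claimants[1]
      if (length(claimants) > 1) {
        for (cand in claimants[-1]) {
          a <- get_track(cand); b <- get_track(winner)
          if (root_beats(a$st_root_intensity, a$st_root_frame, a$st_root_y,
                         a$st_root_x, b$st_root_intensity, b$st_root_frame,
                         b$st_root_y, b$st_root_x))
            winner <- cand
        }
      }
      for (tr_id in claimants) {
        k <- as.character(tr_id)
        if (tr_id == winner) next
        if (!is.null(newborn[[k]])) {
          # a split child losing a merge contest in its birth frame never
          # owned a component; it is discarded rather than recorded
          newborn[[k]] <- NULL
        } else {
          tracks[[tr_id]]$death_frame <- t
          tracks[[tr_id]]$death_cause <- sprintf("merged_into:%d", winner)
          tracks[[tr_id]]$merged_into <- winner
          merges[[length(merges) + 1]] <-
            data.frame(loser = tr_id, winner = winner, frame = t)
        }
      }
      wk <- as.character(winner)
      if (!is.null(newborn[[wk]])) {
        tracks[[winner]] <- newborn[[wk]]
        newborn[[wk]] <- NULL
        edges[[length(edges) + 1]] <-
          data.frame(parent = tracks[[winner]]$parent_id, child = winner,
                     frame = t + 1L)
      } else {
        tr <- tracks[[winner]]
        tr$comps[as.character(t + 1L)] <- cid
        if (root_beats(comp$root_intensity, t + 1L, comp$root_y, comp$root_x,
                       tr$st_root_intensity, tr$st_root_frame, tr$st_root_y,
                       tr$st_root_x)) {
          tr$st_root_intensity <- comp$root_intensity
          tr$st_root_frame <- t + 1L
          tr$st_root_y <- comp$root_y
          tr$st_root_x <- comp$root_x
        }
        tracks[[winner]] <- tr
      }
      new_live[key] <- winner
      claimed[comps_b$id == cid] <- TRUE
    }

    # unclaimed next-frame components found parentless tracks
    if (any(!claimed)) {
      for (i in which(!claimed)) {
        comp <- comps_b[i, ]
        tracks[[next_id]] <- new_track(next_id, NA_integer_, t + 1L, comp)
        new_live[as.character(comp$id)] <- next_id
        next_id <- next_id + 1L
      }
    }
    live <- new_live
    if (length(live) > 0)
      assignment[[t + 1]] <- data.frame(frame = t + 1L,
                                        comp_id = as.integer(names(live)),
                                        track_id = unname(live))
  }

  for (tr_id in unname(live)) {
    tracks[[tr_id]]$death_frame <- nT
    tracks[[tr_id]]$death_cause <- "end_of_video"
  }

  tracks <- Filter(Negate(is.null), tracks)
  track_df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(id = tr$id, parent_id = tr$parent_id,
               birth_frame = tr$birth_frame, death_frame = tr$death_frame,
               death_cause = tr$death_cause, merged_into = tr$merged_into,
               st_root_intensity = tr$st_root_intensity,
               st_root_frame = tr$st_root_frame,
               st_root_y = tr$st_root_y, st_root_x = tr$st_root_x)
  }))
  if (is.null(track_df))
    track_df <- data.frame(id = integer(0), parent_id = integer(0),
                           birth_frame = integer(0), death_frame = integer(0),
                           death_cause = character(0), merged_into = integer(0),
                           st_root_intensity = numeric(0),
                           st_root_frame = integer(0),
                           st_root_y = integer(0), st_root_x = integer(0))
  empty_edges <- data.frame(parent = integer(0), child = integer(0),
                            frame = integer(0))
  empty_merges <- data.frame(loser = integer(0), winner = integer(0),
                             frame = integer(0))
  structure(list(
    tracks = track_df,
    lineage = list(
      edges = if (length(edges)) do.call(rbind, edges) else empty_edges,
      merges = if (length(merges)) do.call(rbind, merges) else empty_merges),
    assignment = if (length(assignment)) do.call(rbind, assignment)
                 else data.frame(frame = integer(0), comp_id = integer(0),
                                 track_id = integer(0)),
    frame_results = frame_results,
    track_comps = lapply(tracks, function(tr) tr$comps)),
    class = "ph_tracks")
}

#' @export
print.ph_tracks <- function(x, ...) {
  cat(sprintf("<ph_tracks> %d frame(s), %d track(s), %d split(s), %d merge(s)\n",
              length(x$frame_results), nrow(x$tracks),
              nrow(x$lineage$edges), nrow(x$lineage$merges)))
  invisible(x)
}

#' Segment and track a video in one call
#'
#' Convenience composition of [segment_frames()] and [link_tracks()].
#'
#' @inheritParams segment_frames
#' @return A `ph_tracks` object, identical to the two-step call.
#' @export
track_video <- function(video, config = seg_config()) {
  link_tracks(segment_frames(video, config))
}

#' Track label maps with stable track identities
#'
#' Relabels each frame's component labels by the track that owns them,
#' so an object keeps one id for its whole life (and a split child's id
#' first appears at its birth frame).
#'
#' @param tracks A `ph_tracks`.
#' @return Integer array (t, y, x) of track ids; 0 is background.
#' @export
track_labels <- function(tracks) {
  nT <- length(tracks$frame_results)
  d2 <- dim(tracks$frame_results[[1]]$labels)
  out <- array(0L, dim = c(nT, d2))
  for (t in seq_len(nT)) {
    asg <- tracks$assignment[tracks$assignment$frame == t, ]
    if (nrow(asg) == 0) next
    lab <- tracks$frame_results[[t]]$labels
    lut <- integer(max(lab) + 1L)
    lut[asg$comp_id + 1L] <- asg$track_id
    out[t, , ] <- array(lut[lab + 1L], dim = d2)
  }
  out
}
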