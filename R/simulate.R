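#' Specification for a synthetic fluorescence stack
#'
#' Describes one simulated z-stack (volume) or t-stack (video) with
#' ground truth, emulating hand-drawn benchmark stacks: 256x256
#' frames, 8-22 frames per stack, a handful of well-separated smooth
#' objects at constant grayscale intensities between 0.5 and 1 over a
#' background of 0, then degraded by Gaussian blur (`blur_sigma`,
#' lateral for videos and isotropic for volumes, in pixels), Gaussian
#' noise (`noise_sigma`, quoted on the 8-bit 0-255 scale as for 8-bit
#' source images), light proportional Gaussian denoising, and
#' renormalization to \[0,1\].
#'
#' Object shapes are randomized deformed ellipsoids (an ellipsoid base
#' plus one or two overlapping lobes); hand-drawn shapes are not
#' recoverable, but these reproduce the relevant structure: smooth,
#' connected, non-convex blobs of varied geometry. The brightest
#' object's intensity is set to exactly 1 so the clean stack is
#' already normalized (and the undegraded pipeline is the identity).
#'
#' @param frame_shape `(height, width)` in pixels.
#' @param n_frames Frames per stack; `NULL` draws from 8-22.
#' @param n_objects Number of objects; `NULL` draws from 3-5.
#' @param intensity_range Object intensity range (default \[0.5, 1\]).
#' @param blur_sigma Blur standard deviation in pixels (0, 5, 10 in
#'   the benchmark grid).
#' @param noise_sigma Noise standard deviation on the 8-bit scale
#'   (0, 5, 10 in the benchmark grid); applied as `noise_sigma/255` on
#'   the unit intensity scale and clipped to \[0,1\].
#' @param denoise_factor Proportionality constant `k` of the denoising
#'   policy: the degraded stack is smoothed with a spatial sigma of
#'   `k * noise_sigma / 10` pixels (1 px of smoothing at noise 10).
#' @param seed Integer seed; the generator is fully deterministic
#'   given the spec.
#' @param mode `"volume"` or `"video"`.
#' @param script For videos: list of scripted events, each a list with
#'   `type = "split"` (`frame`, `object`, `parts`) or `type = "merge"`
#'   (`frame`, `objects` = the two truth ids). `NULL` = no events.
#' @param radius_range Lateral object semi-axis range in pixels.
#' @param axial_radius_range Axial semi-axis range in frames (volumes).
#' @param min_separation Minimum lateral gap between object surfaces;
#'   default `2 * blur_sigma + 3` so degraded objects stay separable.
#' @return A `sim_spec` object.
#' @export
simulation_spec <- function(frame_shape = c(256, 256), n_frames = NULL,
                            n_objects = NULL, intensity_range = c(0.5, 1),
                            blur_sigma = 0, noise_sigma = 0,
                            denoise_factor = 1, seed = 1,
                            mode = c("volume", "video"), script = NULL,
                            radius_range = c(16, 30),
                            axial_radius_range = c(3, 8),
                            min_separation = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 32),
            blur_sigma >= 0, noise_sigma >= 0, denoise_factor >= 0,
            intensity_range[1] > 0, intensity_range[2] <= 1,
            intensity_range[1] < intensity_range[2])
  if (is.null(min_separation)) min_separation <- 2 * blur_sigma + 3
  structure(list(frame_shape = as.integer(frame_shape), n_frames = n_frames,
                 n_objects = n_objects, intensity_range = intensity_range,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 denoise_factor = denoise_factor, seed = as.integer(seed),
                 mode = mode, script = script,
                 radius_range = radius_range,
                 axial_radius_range = axial_radius_range,
                 min_separation = min_separation),
            class = "sim_spec")
}

# ellipsoid + lobes rasterizer; dims/centers in (z,y,x) or (y,x)
rasterize_blob3d <- function(mask, id, cz, cy, cx, rz, ry, rx, lobes) {
  d <- dim(mask)
  ext <- max(ry, rx) * 1.8 + 2
  zs <- max(1, floor(cz - rz - 1)):min(d[1], ceiling(cz + rz + 1))
  ys <- max(1, floor(cy - ext)):min(d[2], ceiling(cy + ext))
  xs <- max(1, floor(cx - ext)):min(d[3], ceiling(cx + ext))
  inside <- outer(outer(((zs - cz) / rz)^2, ((ys - cy) / ry)^2, "+"),
                  ((xs - cx) / rx)^2, "+") <= 1
  for (lb in lobes) {
    inside <- inside |
      (outer(outer(((zs - cz) / (rz * lb$scale))^2,
                   ((ys - (cy + lb$dy)) / (ry * lb$scale))^2, "+"),
             ((xs - (cx + lb$dx)) / (rx * lb$scale))^2, "+") <= 1)
  }
  sub <- mask[zs, ys, xs, drop = FALSE]
  sub[inside] <- id
  mask[zs, ys, xs] <- sub
  mask
}

rasterize_blob2d <- function(mask, id, cy, cx, ry, rx, lobes) {
  d <- dim(mask)
  ext <- max(ry, rx) * 1.8 + 2
  ys <- max(1, floor(cy - ext)):min(d[1], ceiling(cy + ext))
  xs <- max(1, floor(cx - ext)):min(d[2], ceiling(cx + ext))
  inside <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
  for (lb in lobes) {
    inside <- inside |
      (outer(((ys - (cy + lb$dy)) / (ry * lb$scale))^2,
             ((xs - (cx + lb$dx)) / (rx * lb$scale))^2, "+") <= 1)
  }
  sub <- mask[ys, xs, drop = FALSE]
  sub[inside] <- id
  mask[ys, xs] <- sub
  mask
}

sample_lobes <- function(r) {
  n <- sample(1:2, 1)
  lapply(seq_len(n), function(i) {
    ang <- stats::runif(1, 0, 2 * pi)
    off <- 0.6 * r
    list(dy = off * sin(ang), dx = off * cos(ang), scale = 0.55)
  })
}

lobe_extent <- function(r, lobes) {
  ext <- r
  for (lb in lobes)
    ext <- max(ext, sqrt(lb$dy^2 + lb$dx^2) + lb$scale * r)
  ext
}

degrade_stack <- function(clean, spec) {
  axes <- if (spec$mode == "volume") "volume" else "video"
  x <- clean
  d <- dim(x)
  if (spec$blur_sigma > 0) {
    sig <- if (spec$mode == "volume") rep(spec$blur_sigma, 3)
           else c(0, spec$blur_sigma, spec$blur_sigma)
    x <- array(cpp_gaussian_blur(as.numeric(x), as.integer(d), sig), dim = d)
  }
  if (spec$noise_sigma > 0) {
    x <- x + stats::rnorm(length(x), 0, spec$noise_sigma / 255)
    x <- pmin(pmax(x, 0), 1)
    x <- array(x, dim = d)
  }
  stk <- intensity_stack(x, axes)
  sigma_d <- spec$denoise_factor * spec$noise_sigma / 10
  if (sigma_d > 0) stk <- gaussian_denoise(stk, sigma_d)
  if (max(stk$data) > min(stk$data)) stk <- normalize_intensity(stk)
  stk
}

generate_volume <- function(spec) {
  Z <- spec$n_frames
  Y <- spec$frame_shape[1]
  X <- spec$frame_shape[2]
  n <- spec$n_objects
  rr <- spec$radius_range
  ar <- spec$axial_radius_range
  sep <- spec$min_separation

  centers <- matrix(0, n, 2)  # (y, x)
  extents <- numeric(n)
  objs <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(400)) {
      ry <- stats::runif(1, rr[1], rr[2])
      rx <- stats::runif(1, rr[1], rr[2])
      rz <- min(stats::runif(1, ar[1], ar[2]), max(2, (Z - 2) / 2))
      lobes <- sample_lobes(max(ry, rx))
      ext <- lobe_extent(max(ry, rx), lobes)
      if (2 * (ext + 1) + 2 > min(Y, X)) next
      cy <- stats::runif(1, ext + 2, Y - ext - 1)
      cx <- stats::runif(1, ext + 2, X - ext - 1)
      cz <- stats::runif(1, rz + 1, Z - rz)
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        dist <- sqrt(sum((c(cy, cx) - centers[j, ])^2))
        if (dist < ext + extents[j] + sep) { ok <- FALSE; break }
      }
      if (!ok) next
      centers[i, ] <- c(cy, cx)
      extents[i] <- ext
      objs[[i]] <- list(cz = cz, cy = cy, cx = cx, rz = rz, ry = ry, rx = rx,
                        lobes = lobes)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place objects without overlap; use fewer or smaller objects")
  }

  ints <- stats::runif(n, spec$intensity_range[1], spec$intensity_range[2])
  ints[which.max(ints)] <- spec$intensity_range[2]

  idmask <- array(0L, dim = c(Z, Y, X))
  for (i in seq_len(n)) {
    o <- objs[[i]]
    idmask <- rasterize_blob3d(idmask, i, o$cz, o$cy, o$cx, o$rz, o$ry, o$rx,
                               o$lobes)
  }
  clean <- array(0, dim = dim(idmask))
  fg <- idmask > 0
  clean[fg] <- ints[idmask[fg]]
  list(clean = clean, idmask = idmask, intensities = ints)
}

generate_video <- function(spec) {
  nT <- spec$n_frames
  Y <- spec$frame_shape[1]
  X <- spec$frame_shape[2]
  n <- spec$n_objects
  rr <- spec$radius_range
  sep <- spec$min_separation
  script <- if (is.null(spec$script)) list() else spec$script
  for (ev in script) {
    if (!ev$type %in% c("split", "merge")) stop("unknown scripted event type")
    if (ev$frame < 2 || ev$frame > nT) stop("scripted event frame outside video")
  }

  # drawn objects: truth id, frame range, per-frame centres, shape, intensity
  make_paths <- function() {
    ints <- stats::runif(n, spec$intensity_range[1], spec$intensity_range[2])
    ints[which.max(ints)] <- spec$intensity_range[2]
    drawn <- vector("list", n)
    for (i in seq_len(n)) {
      ry <- stats::runif(1, rr[1], rr[2])
      rx <- stats::runif(1, rr[1], rr[2])
      lobes <- sample_lobes(max(ry, rx))
      ext <- lobe_extent(max(ry, rx), lobes)
      v <- stats::runif(2, -1, 1)
      span <- abs(v) * (nT - 1)
      cy <- stats::runif(1, ext + 2 + max(0, -v[1] * (nT - 1)),
                         Y - ext - 1 - max(0, v[1] * (nT - 1)))
      cx <- stats::runif(1, ext + 2 + max(0, -v[2] * (nT - 1)),
                         X - ext - 1 - max(0, v[2] * (nT - 1)))
      centres <- cbind(cy + v[1] * (seq_len(nT) - 1),
                       cx + v[2] * (seq_len(nT) - 1))
      drawn[[i]] <- list(id = i, f0 = 1L, f1 = nT, centres = centres,
                         ry = ry, rx = rx, lobes = lobes, ext = ext,
                         intensity = ints[i], kin = NA_integer_)
    }
    next_id <- n + 1L
    events <- list()
    for (ev in script) {
      f <- as.integer(ev$frame)
      if (ev$type == "split") {
        parts <- if (is.null(ev$parts)) 2L else as.integer(ev$parts)
        pid <- ev$object
        parent <- NULL
        for (dobj in drawn) if (dobj$id == pid && dobj$f1 >= f) parent <- dobj
        if (is.null(parent)) stop("scripted split references a missing object")
        ki <- which(vapply(drawn, function(o) o$id, 0L) == pid &
                      vapply(drawn, function(o) o$f1, 0L) >= f)[1]
        drawn[[ki]]$f1 <- f - 1L
        ang0 <- stats::runif(1, 0, 2 * pi)
        child_ids <- integer(parts)
        for (p in seq_len(parts)) {
          ang <- ang0 + 2 * pi * (p - 1) / parts
          u <- c(sin(ang), cos(ang))
          rc <- 0.55 * max(parent$ry, parent$rx)
          dists <- 0.75 * max(parent$ry, parent$rx) + 2.5 * (f:nT - f)
          centres <- parent$centres
          centres[f:nT, 1] <- centres[f:nT, 1] + u[1] * dists
          centres[f:nT, 2] <- centres[f:nT, 2] + u[2] * dists
          centres[, 1] <- pmin(pmax(centres[, 1], rc + 2), Y - rc - 1)
          centres[, 2] <- pmin(pmax(centres[, 2], rc + 2), X - rc - 1)
          inten <- if (p == 1) parent$intensity
                   else stats::runif(1, spec$intensity_range[1],
                                     spec$intensity_range[2])
          drawn[[length(drawn) + 1]] <-
            list(id = next_id, f0 = f, f1 = nT, centres = centres,
                 ry = rc, rx = rc, lobes = list(), ext = rc,
                 intensity = inten, kin = pid)
          child_ids[p] <- next_id
          next_id <- next_id + 1L
        }
        events[[length(events) + 1]] <-
          list(type = "split", frame = f, parent = pid, children = child_ids)
      } else { # merge
        ids <- ev$objects
        ki <- vapply(ids, function(id)
          which(vapply(drawn, function(o) o$id, 0L) == id)[1], 0L)
        a <- drawn[[ki[1]]]; b <- drawn[[ki[2]]]
        winner <- if (a$intensity >= b$intensity) a else b
        meet <- (a$centres[f, ] + b$centres[f, ]) / 2
        dpre <- (a$ext + b$ext) / 2 + 2
        # approach along straight lines, meeting at frame f
        for (side in 1:2) {
          o <- drawn[[ki[side]]]
          dir <- o$centres[1, ] - meet
          dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
          for (t in seq_len(f - 1)) {
            frac <- if (f > 2) (t - 1) / (f - 2) else 1
            dist0 <- sqrt(sum((o$centres[1, ] - meet)^2))
            o$centres[t, ] <- meet + dir * (dist0 + frac * (dpre - dist0))
          }
          o$f1 <- f - 1L
          drawn[[ki[side]]] <- o
        }
        merged <- winner
        merged$f0 <- f
        merged$f1 <- nT
        merged$centres[f:nT, 1] <- meet[1]
        merged$centres[f:nT, 2] <- meet[2]
        merged$ry <- max(a$ry, b$ry) * 1.1
        merged$rx <- max(a$rx, b$rx) * 1.1
        merged$lobes <- list()
        merged$ext <- max(merged$ry, merged$rx)
        merged$id <- winner$id
        drawn[[length(drawn) + 1]] <- merged
        events[[length(events) + 1]] <-
          list(type = "merge", frame = f, winner = winner$id,
               loser = if (a$intensity >= b$intensity) b$id else a$id)
      }
    }
    list(drawn = drawn, events = events, ints = ints)
  }

  related <- function(a, b) {
    (!is.na(a$kin) && (a$kin == b$id || identical(a$kin, b$kin))) ||
      (!is.na(b$kin) && b$kin == a$id)
  }
  merge_pairs <- do.call(rbind, lapply(script, function(ev)
    if (ev$type == "merge") sort(ev$objects) else NULL))

  ok_config <- FALSE
  for (attempt in seq_len(1000)) {
    cfg <- make_paths()
    drawn <- cfg$drawn
    ok <- TRUE
    for (t in seq_len(nT)) {
      present <- Filter(function(o) o$f0 <= t && t <= o$f1, drawn)
      if (length(present) < 2) next
      for (i in seq_len(length(present) - 1)) for (j in (i + 1):length(present)) {
        a <- present[[i]]; b <- present[[j]]
        dist <- sqrt(sum((a$centres[t, ] - b$centres[t, ])^2))
        interacting <- related(a, b) ||
          (!is.null(merge_pairs) &&
             any(merge_pairs[, 1] == min(a$id, b$id) &
                   merge_pairs[, 2] == max(a$id, b$id)))
        need <- if (interacting) a$ext + b$ext + 1 else a$ext + b$ext + sep
        if (dist < need) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) { ok_config <- TRUE; break }
  }
  if (!ok_config)
    stop("could not place objects without overlap; use fewer or smaller objects")

  idmask <- array(0L, dim = c(nT, Y, X))
  clean <- array(0, dim = c(nT, Y, X))
  for (t in seq_len(nT)) {
    m2 <- array(0L, dim = c(Y, X))
    for (o in cfg$drawn) {
      if (o$f0 > t || t > o$f1) next
      m2 <- rasterize_blob2d(m2, o$id, o$centres[t, 1], o$centres[t, 2],
                             o$ry, o$rx, o$lobes)
    }
    idmask[t, , ] <- m2
  }
  all_ids <- vapply(cfg$drawn, function(o) o$id, 0L)
  all_ints <- vapply(cfg$drawn, function(o) o$intensity, 0)
  lut <- numeric(max(all_ids))
  lut[all_ids] <- all_ints
  fg <- idmask > 0
  clean[fg] <- lut[idmask[fg]]

  n_splits <- sum(vapply(cfg$events, function(e) e$type == "split", TRUE) *
                    vapply(cfg$events, function(e)
                      if (e$type == "split") length(e$children) - 1L else 0L, 0L))
  list(clean = clean, idmask = idmask, intensities = cfg$ints,
       events = cfg$events, expected_tracks = n + n_splits)
}

#' Generate a synthetic stack with ground truth
#'
#' Deterministic given the spec (including its seed). Builds the clean
#' stack, then degrades it: Gaussian blur, additive Gaussian noise
#' clipped to \[0,1\], proportional Gaussian denoising, and affine
#' renormalization. Ground truth reflects the pre-degradation masks.
#'
#' @param spec A [simulation_spec()].
#' @return A `ph_simulation`: list with `degraded` (an
#'   [intensity_stack()]), `truth` (list: `clean` array, `mask` integer
#'   id array, `n_objects`, `expected_count`, and for videos `events`,
#'   `per_frame_counts`, `expected_tracks`) and the resolved `spec`.
#' @export
simulate_stack <- function(spec) {
  if (!inherits(spec, "sim_spec")) stop("`spec` must be a simulation_spec()")
  set.seed(spec$seed)
  if (is.null(spec$n_frames)) spec$n_frames <- sample(8:22, 1)
  if (is.null(spec$n_objects)) spec$n_objects <- sample(3:5, 1)
  spec$n_frames <- as.integer(spec$n_frames)
  spec$n_objects <- as.integer(spec$n_objects)
  if (spec$mode == "volume") {
    g <- generate_volume(spec)
    truth <- list(clean = g$clean, mask = g$idmask,
                  intensities = g$intensities,
                  n_objects = spec$n_objects,
                  expected_count = spec$n_objects)
  } else {
    g <- generate_video(spec)
    nT <- spec$n_frames
    truth <- list(clean = g$clean, mask = g$idmask,
                  intensities = g$intensities,
                  n_objects = spec$n_objects,
                  events = g$events,
                  per_frame_counts = vapply(seq_len(nT), function(t)
                    length(unique(g$idmask[t, , ][g$idmask[t, , ] > 0])),
                    integer(1)),
                  expected_tracks = g$expected_tracks,
                  expected_count = g$expected_tracks)
  }
  degraded <- degrade_stack(g$clean, spec)
  structure(list(degraded = degraded, truth = truth, spec = spec),
            class = "ph_simulation")
}

#' @export
print.ph_simulation <- function(x, ...) {
  cat(sprintf("<ph_simulation> %s %s, %d object(s), sigma1 = %g, sigma2 = %g, seed %d\n",
              x$spec$mode, paste(dim(x$truth$mask), collapse = "x"),
              x$truth$n_objects, x$spec$blur_sigma, x$spec$noise_sigma,
              x$spec$seed))
  invisible(x)
}

#' The 3x3 image-quality condition grid
#'
#' Expands a base spec over blur and noise standard deviations in
#' `{0, 5, 10}` squared, with `replicates` distinct seeds per
#' condition: the benchmark design of 9 conditions x 5 replicates = 45
#' stacks per mode.
#'
#' @param base A [simulation_spec()]; its seed anchors the derived
#'   per-stack seeds.
#' @param replicates Stacks per condition (default 5).
#' @return List of `9 * replicates` specs with distinct seeds.
#' @export
condition_grid <- function(base, replicates = 5) {
  if (!inherits(base, "sim_spec")) stop("`base` must be a simulation_spec()")
  stopifnot(replicates >= 1)
  grid <- expand.grid(sigma1 = c(0, 5, 10), sigma2 = c(0, 5, 10),
                      rep = seq_len(replicates))
  lapply(seq_len(nrow(grid)), function(i) {
    sp <- base
    sp$blur_sigma <- grid$sigma1[i]
    sp$noise_sigma <- grid$sigma2[i]
    sp$min_separation <- 2 * sp$blur_sigma + 3
    sp$seed <- base$seed + 1009L * i
    sp
  })
}
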