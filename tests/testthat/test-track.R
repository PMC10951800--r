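# small helper: build a video stack from a list of (y,x) frames
make_video <- function(frames) {
  arr <- array(0, dim = c(length(frames), dim(frames[[1]])))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  intensity_stack(arr, "video")
}

blob <- function(d, y, x, r, val) {
  m <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    if ((i - y)^2 + (j - x)^2 <= r^2) m[i, j] <- val
  m
}

test_that("per-frame segmentation equals independent 2-D segmentation", {
  v <- make_video(list(blob(c(20, 20), 10, 10, 3, 0.9),
                       blob(c(20, 20), 10, 10, 3, 0.9),
                       matrix(0, 20, 20)))
  fr <- segment_frames(v, seg_config(0.5))
  expect_length(fr, 3)
  expect_identical(fr[[1]]$labels, fr[[2]]$labels)
  solo <- segment_stack(intensity_stack(v$data[1, , ]), seg_config(0.5))
  expect_identical(fr[[1]]$labels, solo$labels)
  expect_equal(n_components(fr[[3]]), 0)
  expect_error(segment_frames(intensity_stack(matrix(0.5, 4, 4))), "video")
})

test_that("one object dividing into two yields a split edge and a child track", {
  f1 <- blob(c(30, 30), 15, 15, 6, 0.9)
  f2 <- blob(c(30, 30), 15, 11, 3, 0.9) + blob(c(30, 30), 15, 19, 3, 0.8)
  tr <- track_video(make_video(list(f1, f2)), seg_config(0.5))
  expect_equal(nrow(tr$tracks), 2)
  t1 <- tr$tracks[tr$tracks$id == 1, ]
  t2 <- tr$tracks[tr$tracks$id == 2, ]
  # the brighter successor continues the parent; the other is its child
  expect_equal(t1$birth_frame, 1)
  expect_equal(t1$death_frame, 2)
  expect_equal(t2$birth_frame, 2)
  expect_equal(t2$parent_id, 1)
  expect_equal(nrow(tr$lineage$edges), 1)
  expect_equal(tr$lineage$edges$frame, 2)
  expect_equal(nrow(tr$lineage$merges), 0)
  # track count including the split matches ground truth of the scenario
  expect_equal(nrow(tr$tracks), 2)
})

test_that("two objects merging kills the dimmer track", {
  f1 <- blob(c(30, 40), 15, 12, 4, 1.0) + blob(c(30, 40), 15, 28, 4, 0.7)
  f2 <- blob(c(30, 40), 15, 20, 12, 1.0)
  tr <- track_video(make_video(list(f1, f2)), seg_config(0.6))
  expect_equal(nrow(tr$tracks), 2)
  winner <- tr$tracks[tr$tracks$id == 1, ]
  loser <- tr$tracks[tr$tracks$id == 2, ]
  expect_equal(winner$death_cause, "end_of_video")
  expect_equal(loser$death_frame, 1)
  expect_equal(loser$death_cause, "merged_into:1")
  expect_equal(nrow(tr$lineage$merges), 1)
  expect_equal(tr$lineage$merges$winner, 1)
  expect_equal(tr$lineage$merges$loser, 2)
})

test_that("identical frames give one track per component spanning the video", {
  f <- blob(c(30, 30), 8, 8, 3, 1.0) + blob(c(30, 30), 22, 22, 3, 0.8)
  tr <- track_video(make_video(list(f, f, f, f)), seg_config(0.5))
  expect_equal(nrow(tr$tracks), 2)
  expect_true(all(tr$tracks$birth_frame == 1))
  expect_true(all(tr$tracks$death_frame == 4))
  expect_true(all(tr$tracks$death_cause == "end_of_video"))
  expect_equal(nrow(tr$lineage$edges), 0)
  expect_equal(nrow(tr$lineage$merges), 0)
})

test_that("track_video equals the two-step composition bitwise", {
  set.seed(21)
  v <- make_video(lapply(1:3, function(i) matrix(runif(100), 10, 10)))
  a <- track_video(v, seg_config(0.4))
  b <- link_tracks(segment_frames(v, seg_config(0.4)))
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$lineage, b$lineage)
  expect_identical(a$assignment, b$assignment)
})

test_that("an all-empty video yields an empty track set", {
  v <- make_video(list(matrix(0, 8, 8), matrix(0, 8, 8)))
  tr <- track_video(v, seg_config(0.5))
  expect_equal(nrow(tr$tracks), 0)
  expect_equal(nrow(tr$lineage$edges), 0)
})

test_that("a vanished object dies with cause vanished", {
  f1 <- blob(c(20, 20), 10, 10, 3, 0.9)
  tr <- track_video(make_video(list(f1, matrix(0, 20, 20), matrix(0, 20, 20))),
                    seg_config(0.5))
  expect_equal(nrow(tr$tracks), 1)
  expect_equal(tr$tracks$death_frame, 1)
  expect_equal(tr$tracks$death_cause, "vanished")
})

test_that("track-frame conservation and lineage forest hold on random videos", {
  for (seed in 1:6) {
    set.seed(seed)
    v <- make_video(lapply(1:4, function(i) matrix(runif(12 * 12), 12, 12)))
    fr <- segment_frames(v, seg_config(0.45))
    tr <- link_tracks(fr)
    # conservation: total track-frames equal total spatial components
    durations <- tr$tracks$death_frame - tr$tracks$birth_frame + 1
    total_comps <- sum(vapply(fr, n_components, integer(1)))
    expect_equal(sum(durations), total_comps)
    # assignment is a bijection per frame
    expect_equal(nrow(tr$assignment), total_comps)
    expect_false(any(duplicated(tr$assignment[, c("frame", "track_id")])))
    expect_false(any(duplicated(tr$assignment[, c("frame", "comp_id")])))
    # forest: at most one parent, children born at their split frame,
    # parent live in the frame before the birth
    e <- tr$lineage$edges
    expect_false(any(duplicated(e$child)))
    if (nrow(e)) {
      for (i in seq_len(nrow(e))) {
        child <- tr$tracks[tr$tracks$id == e$child[i], ]
        parent <- tr$tracks[tr$tracks$id == e$parent[i], ]
        expect_equal(child$birth_frame, e$frame[i])
        expect_lte(parent$birth_frame, e$frame[i] - 1)
        expect_gte(parent$death_frame, e$frame[i] - 1)
      }
    }
    # spatiotemporal root is the running maximum of owned spatial roots
    for (i in seq_len(nrow(tr$tracks))) {
      id <- tr$tracks$id[i]
      asg <- tr$assignment[tr$assignment$track_id == id, ]
      roots <- vapply(seq_len(nrow(asg)), function(r)
        fr[[asg$frame[r]]]$components$root_intensity[
          fr[[asg$frame[r]]]$components$id == asg$comp_id[r]], 0)
      expect_equal(tr$tracks$st_root_intensity[i], max(roots))
    }
  }
})

test_that("reversing a division video swaps splits for merges", {
  f1 <- blob(c(30, 30), 15, 15, 6, 0.9)
  f2 <- blob(c(30, 30), 15, 11, 3, 0.9) + blob(c(30, 30), 15, 19, 3, 0.8)
  f3 <- blob(c(30, 30), 15, 9, 3, 0.9) + blob(c(30, 30), 15, 21, 3, 0.8)
  fwd <- track_video(make_video(list(f1, f2, f3)), seg_config(0.5))
  rev <- track_video(make_video(list(f3, f2, f1)), seg_config(0.5))
  expect_equal(nrow(fwd$tracks), nrow(rev$tracks))
  expect_equal(nrow(fwd$lineage$edges), 1)
  expect_equal(nrow(fwd$lineage$merges), 0)
  expect_equal(nrow(rev$lineage$edges), 0)
  expect_equal(nrow(rev$lineage$merges), 1)
})

test_that("track labels keep stable ids and children appear at birth", {
  f1 <- blob(c(30, 30), 15, 15, 6, 0.9)
  f2 <- blob(c(30, 30), 15, 11, 3, 0.9) + blob(c(30, 30), 15, 19, 3, 0.8)
  tr <- track_video(make_video(list(f1, f2)), seg_config(0.5))
  lab <- track_labels(tr)
  expect_equal(sort(unique(as.integer(lab[1, , ]))), c(0L, 1L))
  expect_equal(sort(unique(as.integer(lab[2, , ]))), c(0L, 1L, 2L))
})
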