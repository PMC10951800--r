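# small stacks keep the generator tests quick; the acceptance suite runs the
# full-size protocol
small_spec <- function(seed, ...) {
  simulation_spec(frame_shape = c(96, 96), n_frames = 8, n_objects = 2,
                  radius_range = c(8, 12), axial_radius_range = c(2, 3),
                  seed = seed, ...)
}

test_that("an undegraded stack is returned exactly as drawn", {
  sim <- simulate_stack(small_spec(3))
  expect_identical(sim$degraded$data, sim$truth$clean)
  vals <- unique(as.numeric(sim$truth$clean))
  expect_true(all(vals == 0 | (vals >= 0.5 & vals <= 1)))
  expect_equal(max(sim$truth$clean), 1)
  # foreground mask and id mask agree
  expect_identical(sim$truth$mask > 0, sim$truth$clean > 0)
  expect_equal(length(unique(sim$truth$mask[sim$truth$mask > 0])),
               sim$truth$n_objects)
})

test_that("generation is deterministic given the spec", {
  a <- simulate_stack(small_spec(11, blur_sigma = 5, noise_sigma = 5))
  b <- simulate_stack(small_spec(11, blur_sigma = 5, noise_sigma = 5))
  expect_identical(a$degraded$data, b$degraded$data)
  expect_identical(a$truth$mask, b$truth$mask)
})

test_that("degradation pipeline stays in [0,1] and spans it", {
  sim <- simulate_stack(small_spec(4, blur_sigma = 5, noise_sigma = 10))
  expect_gte(min(sim$degraded$data), 0)
  expect_equal(max(sim$degraded$data), 1)
  expect_equal(min(sim$degraded$data), 0)
})

test_that("clean stacks are recovered perfectly at tau 0.45", {
  for (seed in c(2, 9)) {
    sim <- simulate_stack(small_spec(seed))
    seg <- segment_stack(sim$degraded, seg_config(0.45))
    expect_equal(n_components(seg), sim$truth$n_objects)
    # label partitions coincide voxel-for-voxel with the truth id masks
    for (k in seg$components$id) {
      vox <- which(seg$labels == k)
      tid <- sim$truth$mask[vox[1]]
      expect_gt(tid, 0)
      expect_identical(vox, which(sim$truth$mask == tid))
    }
  }
})

test_that("a scripted division video logs one split and two final objects", {
  spec <- simulation_spec(frame_shape = c(96, 96), n_frames = 10, n_objects = 1,
                          radius_range = c(9, 12), seed = 5, mode = "video",
                          script = list(list(type = "split", frame = 5,
                                             object = 1, parts = 2)))
  sim <- simulate_stack(spec)
  ev <- sim$truth$events
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "split")
  expect_equal(ev[[1]]$frame, 5)
  expect_length(ev[[1]]$children, 2)
  expect_equal(sim$truth$expected_tracks, 2)
  expect_equal(sim$truth$per_frame_counts, c(rep(1, 4), rep(2, 6)))

  # tracking the clean video reproduces the event log exactly
  tr <- track_video(sim$degraded, seg_config(0.45))
  expect_equal(nrow(tr$tracks), 2)
  expect_equal(nrow(tr$lineage$edges), 1)
  expect_equal(tr$lineage$edges$frame, 5)
  expect_equal(tr$lineage$edges$parent, 1)
  expect_equal(nrow(tr$lineage$merges), 0)
})

test_that("a scripted merge video logs the merge and the winner", {
  spec <- simulation_spec(frame_shape = c(96, 96), n_frames = 10, n_objects = 2,
                          radius_range = c(8, 10), seed = 8, mode = "video",
                          script = list(list(type = "merge", frame = 6,
                                             objects = c(1, 2))))
  sim <- simulate_stack(spec)
  ev <- sim$truth$events
  expect_equal(ev[[1]]$type, "merge")
  expect_equal(ev[[1]]$frame, 6)
  expect_equal(sim$truth$expected_tracks, 2)
  expect_equal(sim$truth$per_frame_counts, c(rep(2, 5), rep(1, 5)))

  tr <- track_video(sim$degraded, seg_config(0.45))
  expect_equal(nrow(tr$tracks), 2)
  expect_equal(nrow(tr$lineage$merges), 1)
  # loser dies on the last frame before the scripted merge
  expect_equal(tr$lineage$merges$frame, 5)
})

test_that("the condition grid covers 3x3 sigma cells with distinct seeds", {
  base <- small_spec(1)
  g5 <- condition_grid(base, 5)
  expect_length(g5, 45)
  g1 <- condition_grid(base, 1)
  expect_length(g1, 9)
  combos <- t(vapply(g1, function(s) c(s$blur_sigma, s$noise_sigma),
                     numeric(2)))
  expect_equal(nrow(unique(combos)), 9)
  expect_true(all(sort(unique(combos[, 1])) == c(0, 5, 10)))
  seeds <- vapply(g5, function(s) s$seed, integer(1))
  expect_false(any(duplicated(seeds)))
  # separation adapts to the cell's blur
  seps <- vapply(g5, function(s) s$min_separation, numeric(1))
  expect_true(all(seps == 2 * vapply(g5, function(s) s$blur_sigma, 0) + 3))
})

test_that("impossible placements error rather than overlap", {
  spec <- simulation_spec(frame_shape = c(48, 48), n_objects = 12,
                          radius_range = c(14, 16), seed = 1)
  expect_error(simulate_stack(spec), "fewer or smaller objects")
})
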