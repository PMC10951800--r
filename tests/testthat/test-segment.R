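test_that("filtration orders by decreasing intensity with lexicographic ties", {
  f <- build_filtration(intensity_stack(matrix(c(0.2, 0.9, 0.5), 1, 3)))
  expect_equal(unname(f$order), rbind(c(1, 2), c(1, 3), c(1, 1)))
  expect_equal(f$intensity, c(0.9, 0.5, 0.2))

  tie <- matrix(0, 3, 3)
  tie[1, 1] <- 0.5
  tie[2, 2] <- 0.5
  f <- build_filtration(intensity_stack(tie))
  expect_equal(unname(f$order[1, ]), c(1, 1))
  expect_equal(unname(f$order[2, ]), c(2, 2))
})

test_that("filtration agrees with a stable-sort oracle on random frames", {
  for (seed in 1:5) {
    x <- rand_stack(seed, c(8, 8), levels = seq(0, 1, by = 0.1))
    f <- build_filtration(intensity_stack(x))
    ord <- oracle_lex_order(x)
    expect_equal(unname(f$order), unname(arrayInd(ord, dim(x))))
  }
})

test_that("sweep rules: attachment, merging and background on a 1x3 row", {
  s <- intensity_stack(matrix(c(1, 0.6, 0.9), 1, 3))
  # generous threshold: 0.6 attaches to the 1.0 root and triggers a merge
  r <- segment_stack(s, seg_config(0.5))
  expect_equal(n_components(r), 1)
  expect_equal(r$components$root_intensity, 1)
  expect_equal(unname(r$labels[1, ]), c(1, 1, 1))
  # strict threshold: 0.6 fails the gate; two singleton components survive
  r <- segment_stack(s, seg_config(0.05))
  expect_equal(n_components(r), 2)
  expect_equal(unname(r$labels[1, ]), c(1, 0, 2))
  expect_equal(r$components$root_intensity, c(1, 0.9))
})

test_that("single maximum and uniform frames segment as expected", {
  img <- matrix(0, 3, 3)
  img[2, 2] <- 1
  r <- segment_stack(intensity_stack(img), seg_config(0.5))
  expect_equal(n_components(r), 1)
  expect_equal(r$components$size, 1)
  expect_equal(r$components$root_intensity, 1)

  u <- segment_stack(intensity_stack(matrix(0.8, 5, 4)), seg_config(0.3))
  expect_equal(n_components(u), 1)
  expect_equal(u$components$size, 20)
  expect_equal(u$components[, c("root_y", "root_x")],
               data.frame(root_y = 1L, root_x = 1L))
})

test_that("segmentation rejects empty and non-normalized input", {
  expect_error(segment_stack(intensity_stack(matrix(1.5, 2, 2))), "normalize")
  expect_error(segment_stack(intensity_stack(matrix(-0.1, 2, 2))), "normalize")
})

test_that("sweep equals the brute-force oracle on random small stacks", {
  cases <- expand.grid(seed = 1:12,
                       shape = list(c(5, 5), c(4, 6), c(4, 4, 4), c(6, 6, 6)),
                       tau = c(0.15, 0.4, 0.75),
                       conn = c("full", "faces"))
  for (i in seq_len(nrow(cases))) {
    dims <- cases$shape[[i]]
    # quantized levels make root ties common, exercising tie-breaks
    x <- rand_stack(cases$seed[i] + 100 * i, dims, levels = seq(0, 1, 0.125))
    r <- segment_stack(intensity_stack(x, if (length(dims) == 2) "frame2d" else "volume"),
                       seg_config(cases$tau[i], as.character(cases$conn[i])))
    lab <- oracle_segment(x, cases$tau[i], cases$conn[i] == "full")
    expect_identical(unname(r$labels), unname(lab),
                     label = sprintf("case %d (seed %d tau %.2f %s)", i,
                                     cases$seed[i], cases$tau[i], cases$conn[i]))
  }
})

test_that("per-component invariants hold on random stacks", {
  for (seed in 1:8) {
    dims <- if (seed %% 2) c(10, 10) else c(5, 8, 8)
    x <- rand_stack(seed, dims)
    tau <- 0.35
    r <- segment_stack(intensity_stack(x, if (length(dims) == 2) "frame2d" else "volume"),
                       seg_config(tau))
    # partition: component sizes match the label map exactly
    tab <- table(factor(r$labels[r$labels > 0], levels = r$components$id))
    expect_equal(as.integer(tab), r$components$size)
    # ids ordered by decreasing root intensity
    expect_true(all(diff(r$components$root_intensity) <= 0))
    for (k in r$components$id) {
      vox <- which(r$labels == k)
      ints <- x[vox]
      # root is the component's arg-max, intensity gap to root bounded by tau
      expect_equal(max(ints), r$components$root_intensity[k])
      expect_lte(r$components$root_intensity[k] - min(ints), tau)
      # background filter
      expect_gte(r$components$root_intensity[k], tau)
    }
  }
})

test_that("component count is non-increasing in tau", {
  taus <- seq(0, 1, length.out = 21)
  for (seed in 1:6) {
    dims <- if (seed %% 2) c(9, 9) else c(4, 7, 7)
    x <- rand_stack(seed, dims)
    s <- intensity_stack(x, if (length(dims) == 2) "frame2d" else "volume")
    counts <- vapply(taus, function(tau)
      n_components(segment_stack(s, seg_config(tau))), integer(1))
    expect_true(all(diff(counts) <= 0),
                label = sprintf("seed %d counts: %s", seed,
                                paste(counts, collapse = " ")))
  }
})

test_that("scaling intensities and tau together preserves the partition", {
  for (seed in 1:5) {
    x <- rand_stack(seed, c(6, 6, 6))
    tau <- 0.4
    base <- segment_stack(intensity_stack(x, "volume"), seg_config(tau))
    for (s in c(0.3, 0.8)) {
      scaled <- segment_stack(intensity_stack(x * s, "volume"),
                              seg_config(tau * s))
      expect_identical(scaled$labels, base$labels)
    }
  }
})

test_that("a single-slice volume segments like its 2-D frame under faces connectivity", {
  x2 <- rand_stack(11, c(12, 12))
  x3 <- array(0, dim = c(3, 12, 12))
  x3[2, , ] <- x2
  r2 <- segment_stack(intensity_stack(x2), seg_config(0.3, "faces"))
  r3 <- segment_stack(intensity_stack(x3, "volume"), seg_config(0.3, "faces"))
  expect_identical(unname(r3$labels[2, , ]), unname(r2$labels))
  expect_true(all(r3$labels[c(1, 3), , ] == 0))
})

test_that("tau calibration starts at 0.5 and bisects to the expected count", {
  # already matching at 0.5: returned unchanged
  s <- intensity_stack(matrix(c(1, 0.6, 0.9), 1, 3))
  cal <- calibrate_tau(s, 1)
  expect_equal(cal$tau, 0.5)
  expect_equal(n_components(cal$result), 1)

  cal <- calibrate_tau(s, 2)
  expect_lt(cal$tau, 0.4)
  expect_equal(n_components(cal$result), 2)

  # unattainable count: warning plus closest achievable
  expect_warning(cal <- calibrate_tau(s, 5), "no threshold")
  expect_lte(abs(n_components(cal$result) - 5),
             abs(1 - 5))
  expect_error(calibrate_tau(s, 0), "positive integer")
})
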