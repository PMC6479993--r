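test_that("reference selection maximises mean correlation, ties to lowest index", {
  t <- seq(0, 1, length.out = 200)
  A <- sin(6 * t) + exp(-((t - 0.5) / 0.05)^2)
  set.seed(4)
  signals <- rbind(A, A + rnorm(200, 0, 0.01), rnorm(200))
  # brute-force correlation matrix agrees on the winner
  C <- cor(t(signals))
  brute <- unname(which.max((rowSums(C) - 1) / 2))
  idx <- select_reference(signals)
  expect_equal(idx, brute)
  expect_true(idx %in% 1:2)  # never the uncorrelated signal

  expect_equal(select_reference(rbind(A, A, A)), 1L)
  expect_equal(select_reference(rbind(A)), 1L)
  expect_error(select_reference(list()), "empty")
})

test_that("COW of a signal onto itself is the identity", {
  x <- toy_signal(121, seed = 1)
  r <- cow_align(x, x, segment_length = 30, slack = 5)
  expect_equal(r$boundary_map[, "source"], r$boundary_map[, "target"])
  expect_equal(r$correlation, 1)
  expect_equal(fusefinger:::fp_values(r$warped), x)
})

test_that("COW recovers a shifted peak within the slack", {
  t <- seq_len(400)
  ref <- exp(-0.5 * ((t - 150) / 12)^2) + exp(-0.5 * ((t - 300) / 15)^2)
  sig <- exp(-0.5 * ((t - 158) / 12)^2) + exp(-0.5 * ((t - 308) / 15)^2)
  expect_lt(cor(sig, ref), 0.96)
  r <- cow_align(sig, ref, segment_length = 50, slack = 10)
  expect_gte(r$correlation, 0.999)
  # boundary map is monotone and endpoint-fixed
  expect_true(all(diff(r$boundary_map[, "source"]) > 0))
  expect_true(all(diff(r$boundary_map[, "target"]) > 0))
  expect_equal(r$boundary_map[1, ], c(source = 1, target = 1))
  expect_equal(r$boundary_map[nrow(r$boundary_map), ],
               c(source = 400, target = 400))
})

test_that("slack zero resamples without freedom", {
  x <- toy_signal(101, seed = 2)
  r <- cow_align(x, x, segment_length = 25, slack = 0)
  expect_equal(fusefinger:::fp_values(r$warped), x)
  # different lengths: pure piecewise-linear resampling
  y <- toy_signal(81, seed = 3)
  r2 <- cow_align(y, x, segment_length = 25, slack = 0)
  expect_length(fusefinger:::fp_values(r2$warped), 101)
})

test_that("the warp DP equals exhaustive enumeration on toy signals", {
  for (seed in 1:4) {
    x <- toy_signal(61, seed = seed)
    ref <- toy_signal(61, seed = seed + 10)
    for (ps in list(c(20, 3), c(15, 2), c(30, 5))) {
      r <- fusefinger:::cow_dp_cpp(x, ref, ps[1], ps[2])
      bf <- cow_bruteforce(x, ref, ps[1], ps[2])
      expect_equal(r$score, bf$score, tolerance = 1e-10)
      expect_equal(r$source, bf$bounds + 1)
    }
  }
})

test_that("warping preserves the reference axis", {
  fp_ref <- fingerprint(seq(0, 60, length.out = 241), toy_signal(241, 5),
                        "LC242")
  fp_sig <- fingerprint(seq(0, 62, length.out = 249), toy_signal(249, 6),
                        "LC242")
  r <- cow_align(fp_sig, fp_ref, 40, 5)
  expect_equal(r$warped$axis, fp_ref$axis)
})

test_that("parameter validation rejects impossible warps", {
  x <- toy_signal(100, 1)
  expect_error(cow_align(x, x, segment_length = 4, slack = 5), "slack")
  expect_error(cow_align(x, x, segment_length = 500, slack = 2),
               "larger than the signal")
})

test_that("grid search honours ranges, constraint and tie-breaking", {
  t <- seq_len(600)
  ref <- exp(-0.5 * ((t - 200) / 10)^2) + exp(-0.5 * ((t - 450) / 14)^2) +
    0.2 * sin(t / 50)
  shift <- 6
  sigs <- lapply(c(4, 6, 5), function(s) {
    exp(-0.5 * ((t - 200 - s) / 10)^2) + exp(-0.5 * ((t - 450 - s) / 14)^2) +
      0.2 * sin((t - s) / 50)
  })
  sr <- grid_search_cow(do.call(rbind, sigs), ref,
                        segment_range = c(20, 100), slack_range = c(2, 10))
  expect_true(sr$best_segment >= 20 && sr$best_segment <= 100)
  expect_true(sr$best_slack >= 2 && sr$best_slack <= 10)
  # recompute the winning candidate's mean correlation directly
  cors <- sapply(sigs, function(s) {
    cow_align(s, ref, sr$best_segment, sr$best_slack)$correlation
  })
  expect_gte(mean(cors), 0.995)
  best_row <- sr$score_grid[sr$score_grid$segment == sr$best_segment &
                              sr$score_grid$slack == sr$best_slack, ]
  expect_equal(best_row$mean_correlation, mean(cors), tolerance = 1e-10)

  # degenerate single-candidate range returns that candidate
  sr1 <- grid_search_cow(do.call(rbind, sigs), ref,
                         segment_range = c(50, 50), slack_range = c(8, 8))
  expect_equal(c(sr1$best_segment, sr1$best_slack), c(50, 8))

  # an impossible area tolerance fails loudly
  expect_error(grid_search_cow(do.call(rbind, sigs), ref,
                               segment_range = c(20, 100),
                               slack_range = c(2, 10), area_tol = 0),
               "search failed")
})

test_that("one-in-three reduction keeps the first point of each triple", {
  fp <- fingerprint(seq(0, 60, length.out = 7201), rnorm(7201), "LC242")
  b <- bin_every_third(fp)
  expect_length(b$values, 2401)
  expect_equal(b$values[1:3], fp$values[c(1, 4, 7)])
  fp2 <- fingerprint(seq(0, 65, length.out = 7801), rnorm(7801), "LC242")
  expect_length(bin_every_third(fp2)$values, 2601)
  fp3 <- fingerprint(c(0, 1, 2), c(5, 6, 7), "LC242")
  expect_length(bin_every_third(fp3)$values, 1)
})

test_that("the 11-minute crop is inclusive and yields the final sizes", {
  ax <- seq(0, by = 1.5 / 60, length.out = 2401)  # 1.5 s spacing
  fp <- fingerprint(ax, rnorm(2401), "LC242")
  cr <- crop_initial(fp, 11)
  expect_length(cr$values, 1960)
  expect_true(all(cr$axis > 11))
  ax2 <- seq(0, by = 1.5 / 60, length.out = 2601)
  expect_length(crop_initial(fingerprint(ax2, rnorm(2601), "LC242"))$values,
                2160)
  expect_equal(crop_initial(fp, -1)$values, fp$values)
  expect_error(crop_initial(fp, 999), "empty")
})

test_that("block preprocessing runs align, then bin, then crop", {
  p <- sim_params()
  d <- make_design()
  rows <- d[d$part == "inner", ][seq(1, 78, by = 13), ]
  rownames(rows) <- NULL
  M <- t(sapply(seq_len(nrow(rows)), function(i) {
    simulate_chromatogram(rows[i, ], "LC242", p,
                          seed = 100 + i)$values
  }))
  b <- block(M, rows, fusefinger:::chrom_axis("inner"), "LC242-inner")
  pr <- align_bin_crop(b, segment_length = 100, slack = 5)
  expect_equal(attr(pr$block, "steps"), c("align", "bin", "crop"))
  expect_equal(ncol(pr$block$matrix), 1960)
  expect_gte(pr$mean_correlation, 0.99)
  expect_length(pr$correlations, nrow(rows))
})
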