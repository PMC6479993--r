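test_that("study design matches the sampling plan", {
  d <- make_design(0)
  expect_equal(nrow(d), 156)
  expect_equal(length(unique(d$sclerotium_id)), 78)
  expect_equal(unname(table(d$part)), c(78L, 78L),
               ignore_attr = TRUE)
  # exactly two samples (one per part) share each sclerotium
  per_scl <- table(d$sclerotium_id)
  expect_true(all(per_scl == 2))
  parts_per_scl <- tapply(d$part, d$sclerotium_id,
                          function(p) length(unique(p)))
  expect_true(all(parts_per_scl == 2))
  # class sizes: 10 sclerotia for classes 1-7, 8 for class 8
  sizes <- tapply(d$sclerotium_id, d$class_label,
                  function(s) length(unique(s)))
  expect_equal(as.numeric(sizes), c(10, 10, 10, 10, 10, 10, 10, 8))
  # the design is fixed: independent of the seed
  expect_identical(d, make_design(123))
})

test_that("chromatogram simulation produces the stated grids", {
  p <- sim_params()
  d <- make_design()
  inner <- d[d$part == "inner", ][1, ]
  epi <- d[d$part == "epidermis", ][1, ]
  fi <- simulate_chromatogram(inner, "LC242", p, seed = 3)
  fe <- simulate_chromatogram(epi, "LC242", p, seed = 3)
  expect_length(fi$values, 7201)
  expect_length(fe$values, 7801)
  expect_equal(fi$axis[1], 0)
  expect_equal(fi$axis[7201], 60)
  expect_equal(fe$axis[7801], 65)
  expect_error(simulate_chromatogram(inner, "FTIR", p, 1), "LC242 or LC210")
})

test_that("noise-free same-class chromatograms are identical, other classes differ", {
  p <- sim_params(retention_shift_sd = 0, noise_sd = 0, within_sd = 0,
                  intensity_sd = 0)
  d <- make_design()
  s1 <- d[d$part == "inner" & d$class_label == 2, ][1, ]
  s2 <- d[d$part == "inner" & d$class_label == 2, ][2, ]
  s3 <- d[d$part == "inner" & d$class_label == 6, ][1, ]
  f1 <- simulate_chromatogram(s1, "LC242", p, seed = 1)
  f2 <- simulate_chromatogram(s2, "LC242", p, seed = 99)
  f3 <- simulate_chromatogram(s3, "LC242", p, seed = 1)
  expect_equal(f1$values, f2$values)
  expect_gt(sqrt(mean((f1$values - f3$values)^2)), 0)
})

test_that("cross-correlation lag between two runs matches their drawn shifts", {
  p <- sim_params(retention_shift_sd = 2, noise_sd = 0, within_sd = 0,
                  intensity_sd = 0)
  d <- make_design()
  s1 <- d[d$part == "inner" & d$class_label == 4, ][1, ]
  s2 <- d[d$part == "inner" & d$class_label == 4, ][2, ]
  f1 <- simulate_chromatogram(s1, "LC242", p, seed = 11)
  f2 <- simulate_chromatogram(s2, "LC242", p, seed = 12)
  # a positive shift delays the run: f1(t) = g(t - d1), so the lag that
  # matches f1 to f2 is (d2 - d1) in sampling steps
  dlag_pts <- (attr(f2, "shift_s") - attr(f1, "shift_s")) / 0.5
  lags <- -60:60
  cc <- sapply(lags, function(L) {
    i <- seq(500, 6500)
    cor(f1$values[i], f2$values[i + L])
  })
  expect_lte(abs(lags[which.max(cc)] - dlag_pts), 1)
})

test_that("FTIR spectra have the stated axis and part-specific bands", {
  p <- sim_params()
  d <- make_design()
  inner <- d[d$part == "inner" & d$class_label == 1, ][1, ]
  epi <- d[d$part == "epidermis" & d$class_label == 1, ][1, ]
  sp <- simulate_spectrum(inner, p, seed = 2)
  expect_length(sp$axis, (4000 - 650) / 2 + 1)  # 1676
  expect_equal(sp$axis[1], 4000)
  expect_equal(sp$axis[length(sp$axis)], 650)

  # at 1704 cm^-1 the inner part shows baseline + noise only
  p0 <- sim_params(noise_sd = 0, within_sd = 0, intensity_sd = 0)
  si <- simulate_spectrum(inner, p0, seed = 2)
  se <- simulate_spectrum(epi, p0, seed = 2)
  at <- function(fp, wn) fp$values[which.min(abs(fp$axis - wn))]
  baseline <- 0.01 * 1704 / 4000
  expect_lt(abs(at(si, 1704) - baseline), 0.02)       # nothing but baseline
  expect_gt(at(se, 1704) - baseline, 0.1)             # real band in the cutis
  # noiseless spectra equal the class/part template exactly
  si2 <- simulate_spectrum(inner, p0, seed = 77)
  expect_equal(si$values, si2$values)
})

test_that("simulate_study is reproducible and row-aligned across channels", {
  p <- sim_params()
  s1 <- simulate_study(p, seed = 5)
  s2 <- simulate_study(p, seed = 5)
  expect_identical(s1$blocks, s2$blocks)
  expect_equal(length(s1$blocks), 6)
  for (part in c("inner", "epidermis")) {
    ids <- paste0(c("LC242", "LC210", "FTIR"), "-", part)
    orders <- lapply(s1$blocks[ids], function(b) b$row_meta$sample_id)
    expect_true(all(sapply(orders[-1], identical, orders[[1]])))
    expect_equal(nrow(s1$blocks[[ids[1]]]$matrix), 78)
  }
  expect_equal(ncol(s1$blocks[["LC242-inner"]]$matrix), 7201)
  expect_equal(ncol(s1$blocks[["LC242-epidermis"]]$matrix), 7801)
  # both LC channels of one injection share the drawn shift
  expect_equal(attr(s1$blocks[["LC242-inner"]], "shift_s"),
               attr(s1$blocks[["LC210-inner"]], "shift_s"))
})

test_that("study export writes one CSV per block plus metadata and manifest", {
  p <- sim_params()
  s <- simulate_study(p, seed = 1)
  # shrink for IO speed: keep 3 samples per block
  s$blocks <- lapply(s$blocks, function(b) {
    b$matrix <- b$matrix[1:3, , drop = FALSE]
    b$row_meta <- b$row_meta[1:3, , drop = FALSE]
    b
  })
  dir <- withr::local_tempdir()
  mf <- write_study(s, dir)
  expect_true(file.exists(mf))
  man <- jsonlite::read_json(mf)
  expect_length(man$blocks, 6)
  b1 <- utils::read.csv(file.path(dir, man$blocks[["LC242-inner"]]),
                        check.names = FALSE)
  expect_equal(names(b1)[1], "axis")
  expect_equal(ncol(b1), 4)
  expect_equal(nrow(b1), 7201)
})
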