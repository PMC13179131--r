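test_that("spillover slope is recovered from secondary-only controls", {
  # injected s = 0.05, 2% noise -> within 5% relative
  sr <- small_render(seed = 2, s = 0.05, noise_sd = 0.02 * 200)
  fit <- fit_spillover(sr$st$channels$marker, sr$st$channels$mcherry, sr$mask)
  expect_lt(abs(fit$s - 0.05) / 0.05, 0.05)

  # injected s = 0 -> |s| within 3 standard errors
  sr0 <- small_render(seed = 3, s = 0, noise_sd = 0.02 * 200)
  fit0 <- fit_spillover(sr0$st$channels$marker, sr0$st$channels$mcherry,
                        sr0$mask)
  expect_lt(abs(fit0$s), 3 * fit0$se)

  # doubling B and its bleed contribution jointly leaves s unchanged
  st <- sr$st
  marker2 <- st$channels$marker + fit$s * st$channels$mcherry
  fit2 <- fit_spillover(marker2, 2 * st$channels$mcherry, sr$mask)
  expect_equal(fit2$s, fit$s, tolerance = 1e-12)

  # degenerate bleed channel
  expect_error(fit_spillover(st$channels$marker,
                             array(1, dim(st$channels$marker)), sr$mask),
               "zero variance")
})

test_that("per-plane offsets are recovered exactly and robustly", {
  off <- function(z) 10 + 0.5 * (z - min(z))
  sr <- small_render(seed = 4, s = 0.05, noise_sd = 0, offsets = off)
  b0 <- estimate_plane_offsets(sr$st$channels$marker, sr$st$channels$mcherry,
                               sr$mask, 0.05)
  filled <- which(!attr(b0, "interpolated"))
  expect_equal(as.numeric(b0[filled]), sr$st$truth$b0[filled],
               tolerance = 1e-9)

  # 20% large positive outliers: medians hold within 2%
  st <- sr$st
  marker_c <- st$channels$marker
  set.seed(5)
  idx <- which(sr$mask)
  bad <- sample(idx, round(0.2 * length(idx)))
  marker_c[bad] <- marker_c[bad] + 500
  b0c <- estimate_plane_offsets(marker_c, st$channels$mcherry, sr$mask, 0.05)
  rel <- abs(b0c[filled] - st$truth$b0[filled]) / abs(st$truth$b0[filled])
  expect_lt(max(rel), 0.02)

  # s = 0 reduces to the per-plane median of the observed channel
  b00 <- estimate_plane_offsets(st$channels$marker, st$channels$mcherry,
                                sr$mask, 0)
  for (z in filled[c(1, 5, 9)]) {
    m <- sr$mask[, , z]
    expect_equal(b00[[z]], median(st$channels$marker[, , z][m]))
  }
})

test_that("correction removes the bleed dependence on secondary-only data", {
  sr <- small_render(seed = 6, s = 0.08, noise_sd = 0.01 * 200)
  st <- sr$st
  fit <- fit_spillover(st$channels$marker, st$channels$mcherry, sr$mask)
  b0 <- estimate_plane_offsets(st$channels$marker, st$channels$mcherry,
                               sr$mask, fit$s)
  mdl <- spillover_model(fit, b0)
  corr <- correct_channel(st$channels$marker, st$channels$mcherry, mdl)

  # per-plane median of corrected secondary-only signal ~ 0
  for (z in which(!attr(b0, "interpolated"))) {
    m <- sr$mask[, , z]
    expect_lt(abs(median(corr[, , z][m])), 0.02 * 200)
  }
  # residual slope of corrected on bleed ~ 0
  refit <- fit_spillover(corr, st$channels$mcherry, sr$mask)
  expect_lt(abs(refit$s), 3 * refit$se + 1e-3)

  # identity model
  id <- spillover_model(0, rep(0, dim(st$channels$marker)[3]))
  expect_identical(correct_channel(st$channels$marker, st$channels$mcherry,
                                   id),
                   st$channels$marker)
})

test_that("corrected per-cell means recover true marker levels on a mosaic", {
  g <- generate_point_gastruloid(
    200, 0.5, geometry_params = list(semi_axes = c(26, 24, 18)),
    nucleus_diameter = 4, seed = 7)
  st <- render_image_stack(g, nucleus_radii = c(2, 2, 2.5), spillover_s = 0.05,
                           plane_offsets = function(z) 10 + 0.5 * (z - min(z)),
                           noise_sd = 0, dims = c(64, 64, 20))
  mask <- st$labels$mcherry > 0 | st$labels$emirfp > 0
  mdl <- spillover_model(0.05, st$truth$b0)
  corr <- correct_channel(st$channels$marker, st$channels$mcherry, mdl)
  lab <- pmax(st$labels$mcherry, st$labels$emirfp)
  means <- nuclear_means(corr, lab)
  truth <- g$cells$marker_level[match(as.integer(names(means)),
                                      g$cells$cell_id)]
  expect_equal(as.numeric(means), truth, tolerance = 1e-9)

  # correlation with truth beats the uncorrected means when s > 0
  means_raw <- nuclear_means(st$channels$marker, lab)
  expect_gt(cor(as.numeric(means), truth), cor(as.numeric(means_raw), truth))
})

test_that("nuclear means reduce to simple averages", {
  m <- matrix(7, 4, 4)
  expect_equal(nuclear_mean(m, matrix(TRUE, 4, 4)), 7)
  chk <- matrix(c(2, 8), 4, 4)           # checkerboard by recycling
  expect_equal(nuclear_mean(chk, matrix(TRUE, 4, 4)), 5)
  set.seed(8)
  v <- matrix(runif(64), 8, 8); msk <- matrix(runif(64) > 0.5, 8, 8)
  expect_equal(nuclear_mean(v, msk), sum(v[msk]) / sum(msk))
  expect_error(nuclear_mean(v, matrix(FALSE, 8, 8)), "empty")
})

test_that("Tukey fences flag strictly above tau with type-7 quartiles", {
  # plane {1,2,3,4} plus one planted value: with the plant included the
  # type-7 quartiles are Q1 = 2, Q3 = 4, so tau = 4 + 4.5*2 = 13 and a
  # plant at Q3 + 5*IQR = 14 is the only flagged value
  vals <- c(1, 2, 3, 4, 14)
  cl <- classify_extreme_high(vals, rep(1L, 5))
  expect_equal(cl$fences$tau, 13)
  expect_equal(cl$high, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # a value exactly at tau is not flagged (strict inequality)
  cl_eq <- classify_extreme_high(c(1, 2, 3, 4, 13), rep(1L, 5))
  expect_false(any(cl_eq$high))

  # IQR = 0: only values strictly above the common value flagged
  cl0 <- classify_extreme_high(c(5, 5, 5, 5, 5, 6), rep(1L, 6))
  expect_equal(cl0$high, c(rep(FALSE, 5), TRUE))

  # thresholds are per plane
  v <- c(rnorm(50, 10, 1), rnorm(50, 100, 1))
  pl <- rep(1:2, each = 50)
  cl2 <- classify_extreme_high(v, pl)
  expect_equal(nrow(cl2$fences), 2)
  expect_false(any(cl2$high))

  # small planes merge with a neighbour
  cl3 <- classify_extreme_high(c(rnorm(20), rnorm(2)), rep(c(1L, 2L),
                                                           c(20, 2)))
  expect_equal(cl3$fences$merged_into, c(1L, 1L))
})

test_that("null extreme-high rate on Gaussian planes is far below 0.1%", {
  set.seed(9)
  pl <- sample(1:20, 10000, replace = TRUE)
  v <- rnorm(10000, 100, 10)
  cl <- classify_extreme_high(v, pl)
  expect_lt(mean(cl$high), 0.001)
})

test_that("population disambiguation separates, excludes mismatches, ignores order", {
  g <- generate_point_gastruloid(600, 0.5, seed = 10)
  X <- cbind(mcherry = g$cells$mcherry_level, emirfp = g$cells$emirfp_level)
  ap <- assign_population(X, g$cells$population)
  expect_equal(ap$population, g$cells$population)
  expect_false(any(ap$excluded))

  # 5% planted channel swaps are excluded
  set.seed(11)
  swap <- sample(600, 30)
  X2 <- X; X2[swap, ] <- X[swap, 2:1]
  ap2 <- assign_population(X2, g$cells$population)
  expect_true(all(ap2$excluded[swap]))
  expect_false(any(ap2$excluded[-swap]))

  # permutation invariance
  perm <- sample(600)
  ap3 <- assign_population(X[perm, ], g$cells$population[perm])
  expect_equal(ap3$population, ap$population[perm])

  expect_error(assign_population(matrix(1, 5, 2), rep("mCherry", 5)),
               "collapse")
})

test_that("nuclear/cytoplasmic ratio subtracts backgrounds per compartment", {
  nmask <- matrix(FALSE, 20, 20); nmask[8:12, 8:12] <- TRUE
  mmask <- matrix(FALSE, 20, 20); mmask[5:15, 5:15] <- TRUE

  ch <- matrix(3, 20, 20)
  expect_equal(yap_nc_ratio(ch, nmask, mmask)$ratio, 1)

  ch2 <- matrix(0, 20, 20); ch2[nmask] <- 8; ch2[mmask & !nmask] <- 4
  expect_equal(yap_nc_ratio(ch2, nmask, mmask)$ratio, 2)

  # injected ratio 1.6 with nonzero backgrounds, recovered after subtraction
  set.seed(12)
  nuc_bg <- 3; cyt_bg <- 1.5; cyt_sig <- 10
  ch3 <- matrix(0, 20, 20)
  ch3[nmask] <- 1.6 * cyt_sig + nuc_bg + rnorm(sum(nmask), 0, 0.05)
  ch3[mmask & !nmask] <- cyt_sig + cyt_bg +
    rnorm(sum(mmask & !nmask), 0, 0.05)
  r <- yap_nc_ratio(ch3, nmask, mmask, nuclear_bg = nuc_bg, cyto_bg = cyt_bg)
  expect_equal(r$ratio, 1.6, tolerance = 0.02)

  # non-positive denominator flags
  rbad <- yap_nc_ratio(ch2, nmask, mmask, cyto_bg = 10)
  expect_true(rbad$flagged)
  expect_true(is.na(rbad$ratio))
  expect_error(yap_nc_ratio(ch2, matrix(FALSE, 20, 20), mmask), "empty")
})

test_that("injected extreme-marker fraction is recovered within binomial error", {
  g <- generate_point_gastruloid(2000, 0.5, extreme_fraction = 0.03,
                                 seed = 14)
  cl <- classify_extreme_high(g$cells$marker_level, g$cells$plane,
                              min_per_plane = 10)
  f <- mean(cl$high)
  tol <- 3 * sqrt(0.03 * 0.97 / 2000)
  expect_lt(abs(f - 0.03), tol + 0.01)
  # and the flagged set is enriched in true extremes
  expect_gt(mean(g$cells$marker_extreme[cl$high]), 0.9)
})
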