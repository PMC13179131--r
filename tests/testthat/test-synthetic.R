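test_that("point generator is deterministic and respects degenerate inputs", {
  g1 <- generate_point_gastruloid(500, 0.5, seed = 1)
  g2 <- generate_point_gastruloid(500, 0.5, seed = 1)
  expect_identical(g1$cells, g2$cells)
  expect_identical(g1$geometry$boundaries, g2$geometry$boundaries)

  g <- generate_point_gastruloid(1, 1, geometry_params =
                                   list(semi_axes = c(50, 50, 50)), seed = 7)
  expect_equal(nrow(g$cells), 1)
  expect_equal(g$cells$population, "mCherry")
  expect_lt(sqrt(sum(g$cells[1, c("x", "y", "z")]^2)), 50)
})

test_that("population mixing matches the Bernoulli design within binomial error", {
  n <- 2000; p <- 0.14
  g <- generate_point_gastruloid(n, p, seed = 3)
  sd_binom <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(g$cells$population == "mCherry") - p), 3 * sd_binom)
})

test_that("cell centres lie strictly inside their centre-plane boundary", {
  g <- generate_point_gastruloid(400, 0.5, seed = 9)
  geo <- g$geometry
  ip <- vapply(g$cells$z, function(z) which.min(abs(geo$z_um - z)), integer(1))
  inside <- vapply(seq_len(nrow(g$cells)), function(i)
    point_in_polygon(g$cells$x[i], g$cells$y[i], geo$boundaries[[ip[i]]]),
    logical(1))
  expect_true(all(inside))
  # hard-core spacing holds
  D <- as.matrix(dist(g$cells[, c("x", "y", "z")]))
  diag(D) <- Inf
  expect_gte(min(D), g$truth$hardcore - 1e-9)
})

test_that("too-small geometry raises a placement-failure error", {
  expect_error(
    generate_point_gastruloid(500, 0.5, geometry_params =
                                list(semi_axes = c(15, 15, 10)), seed = 1),
    "placement failure")
})

test_that("render with no spillover, offsets or noise is the identity on the marker", {
  g <- generate_point_gastruloid(100, 0.5, geometry_params =
                                   list(semi_axes = c(40, 35, 25)), seed = 4)
  st <- render_image_stack(g, spillover_s = 0, plane_offsets = 0, noise_sd = 0)
  expect_identical(st$channels$marker, st$channels$marker_true)
})

test_that("secondary-only render follows the closed-form injection model per plane", {
  sr <- small_render(seed = 5, s = 0.05, noise_sd = 0, secondary_only = TRUE)
  st <- sr$st
  nz <- dim(st$channels$marker)[3]
  for (z in seq_len(nz)) {
    expect_equal(mean(st$channels$marker[, , z]),
                 st$truth$b0[z] + 0.05 * mean(st$channels$mcherry[, , z]),
                 tolerance = 1e-12)
  }
})

test_that("label masks conserve the cell count", {
  g <- generate_point_gastruloid(300, 0.4, seed = 6)
  st <- render_image_stack(g, noise_sd = 0)
  ids <- sort(unique(c(st$labels$mcherry[st$labels$mcherry > 0],
                       st$labels$emirfp[st$labels$emirfp > 0])))
  expect_equal(ids, g$cells$cell_id)
  # channel split matches populations
  mch_ids <- unique(st$labels$mcherry[st$labels$mcherry > 0])
  expect_setequal(mch_ids, g$cells$cell_id[g$cells$population == "mCherry"])
})

test_that("count time course: determinism, closed form, and gate stagnation", {
  d <- count_design(competition = FALSE, seeding = c(mCherry = 150, emiRFP = 150))
  expect_identical(generate_count_timecourse(d, seed = 2),
                   generate_count_timecourse(d, seed = 2))

  # noiseless closed form: N(24 h) = 150 * exp(r * 24)
  d0 <- count_design(competition = FALSE, noise = "none",
                     seeding = c(mCherry = 150, emiRFP = 150),
                     times = c(0, 24), n_gastruloids = 3)
  ct <- generate_count_timecourse(d0, seed = 1)
  r <- d0$rates[["mCherry"]]
  got <- ct$count[ct$population == "mCherry" & ct$time_h == 24]
  expect_equal(got, rep(round(150 * exp(r * 24)), 3))

  # Poisson noise stays within 4 s.d. of the closed form
  dp <- count_design(competition = FALSE, times = c(0, 24),
                     seeding = c(mCherry = 150, emiRFP = 150),
                     n_gastruloids = 24)
  ctp <- generate_count_timecourse(dp, seed = 3)
  mu <- 150 * exp(r * 24)
  got <- ctp$count[ctp$population == "mCherry" & ctp$time_h == 24]
  expect_lt(abs(mean(got) - mu), 4 * sqrt(mu / 24))

  # stagnation rate 0 freezes the loser inside the gate (noiseless)
  dg <- count_design(competition = TRUE, noise = "none",
                     stagnation_rate = 0, times = c(0, 48, 96, 120))
  ctg <- generate_count_timecourse(dg, seed = 1)
  loser <- ctg[ctg$population == "mCherry", ]
  expect_equal(loser$count[loser$time_h == 96],
               loser$count[loser$time_h == 48])

  expect_error(generate_count_timecourse(
    count_design(rates = c(mCherry = -0.1, emiRFP = 0.1))), "negative")
})

test_that("reference pseudobulk stores exact truth at zero noise", {
  pb <- generate_reference_pseudobulk(100, 4, noise_sd = 0, alphas = 0.3,
                                      seed = 11)
  expect_identical(pb, generate_reference_pseudobulk(100, 4, noise_sd = 0,
                                                     alphas = 0.3, seed = 11))
  # queries at zero noise equal the stage centroids
  expect_equal(unname(pb$queries), unname(pb$reference), tolerance = 1e-12)
  # mixture query is the exact mixture
  expect_equal(as.numeric(pb$mixture_queries[, 1]),
               as.numeric(0.3 * pb$posterior + 0.7 * pb$anterior),
               tolerance = 1e-12)
  expect_error(generate_reference_pseudobulk(5, 4), "10 genes")
  expect_error(generate_reference_pseudobulk(100, 1), "2 stages")
})

test_that("stack files round-trip through the TIFF writers", {
  g <- generate_point_gastruloid(60, 0.5, geometry_params =
                                   list(semi_axes = c(30, 28, 20)), seed = 12)
  st <- render_image_stack(g, noise_sd = 0)
  dir <- withr::local_tempdir()
  files <- write_synthetic_stack(g, st, dir)
  lab <- read_label_stack(file.path(dir, "labels_mcherry.tif"))
  expect_identical(dim(lab), dim(st$labels$mcherry))
  expect_identical(lab, st$labels$mcherry)
  cells <- read_cell_table(file.path(dir, "cells.csv"))
  expect_equal(cells$x, g$cells$x)
})
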