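## Synthetic mosaic-gastruloid generator.
##
## Emulates the data the imaging pipeline consumes -- two fluorescently
## distinct nuclear populations mixed in an irregular 3D aggregate, bimodal
## channel intensities with linear spillover and a depth-dependent baseline,
## a small extreme-high marker fraction, staged apoptotic events, and
## competition count time courses -- with full ground truth, so every
## downstream stage is testable without raw microscopy data.

#' Run code with a locally-seeded RNG, restoring global state afterwards
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Polar-form boundary radius of the deformed ellipsoid at polar angle phi
## and height fraction hz in [0,1]: ellipse polar radius times a smooth
## angular deformation, scaled by the ellipsoid height factor.
shape_radius <- function(phi, hz, a, b, amps, phases) {
  e <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  s <- rep(1, length(phi))
  for (k in seq_along(amps)) s <- s + amps[k] * cos((k + 1) * phi + phases[k])
  e * s * hz
}

#' Generate a synthetic mosaic gastruloid as a point cloud with ground truth
#'
#' Samples `n_cells` nucleus centres inside a smoothly deformed ellipsoid
#' with a hard-core minimum spacing, assigns each cell to one of two
#' populations (`"mCherry"` / `"emiRFP"`), and draws per-cell channel and
#' marker intensities from separable log-normal distributions. A small
#' fraction of cells carries an extreme-high marker level. Per-plane
#' boundary polygons (the reference frame for radial statistics) are emitted
#' alongside.
#'
#' @param n_cells number of cells to place (>= 1).
#' @param mix_fraction expected fraction of the `"mCherry"` population.
#' @param geometry_params list with elements `semi_axes` (µm, length 3),
#'   `deform_amp` (total amplitude of the angular deformation), `z_step`
#'   (plane spacing, µm) and `n_boundary` (vertices per boundary polygon).
#' @param nucleus_diameter nominal nucleus diameter in µm; the hard-core
#'   minimum centre spacing is `hardcore_frac` times this.
#' @param hardcore_frac hard-core spacing as a fraction of the nucleus
#'   diameter.
#' @param radial_bias log-odds shift of the mCherry assignment probability
#'   with relative radial position (0 = spatially uniform mixing, the
#'   default; positive values bias mCherry cells outward).
#' @param extreme_fraction expected fraction of cells with an extreme-high
#'   marker level.
#' @param seed integer RNG seed; identical seeds reproduce the output
#'   bit-for-bit.
#' @return an object of class `synthetic_gastruloid`: a list with `cells`
#'   (data frame of centres, population labels and true intensity levels),
#'   `geometry` (a [gastruloid_geometry] object) and `truth` (the generator
#'   parameters, including realised extreme ids).
#' @export
generate_point_gastruloid <- function(n_cells,
                                      mix_fraction = 0.5,
                                      geometry_params = list(),
                                      nucleus_diameter = 8,
                                      hardcore_frac = 0.8,
                                      radial_bias = 0,
                                      extreme_fraction = 0.02,
                                      seed = 1L) {
  check_that(n_cells >= 1, "n_cells must be >= 1")
  check_that(mix_fraction >= 0 && mix_fraction <= 1,
             "mix_fraction must be in [0, 1]")
  gp <- utils::modifyList(list(semi_axes = c(80, 65, 50), deform_amp = 0.12,
                               z_step = 2, n_boundary = 96), geometry_params)
  a <- gp$semi_axes[1]; b <- gp$semi_axes[2]; cc <- gp$semi_axes[3]
  check_that(all(gp$semi_axes > 0) && gp$z_step > 0, "geometry must be positive")
  hardcore <- hardcore_frac * nucleus_diameter
  margin <- nucleus_diameter / 2

  with_seed(seed, {
    n_harm <- 3L
    amps <- gp$deform_amp * abs(stats::rnorm(n_harm)) / n_harm
    phases <- stats::runif(n_harm, 0, 2 * pi)

    zmax <- floor((cc * 0.999) / gp$z_step) * gp$z_step
    z_planes <- seq(-zmax, zmax, by = gp$z_step)

    ## rejection sampling with hard-core spacing
    pts <- matrix(NA_real_, n_cells, 3)
    rfrac <- numeric(n_cells)
    plane_idx <- integer(n_cells)
    placed <- 0L
    attempts <- 0L
    max_attempts <- max(5e4, 500L * n_cells)
    while (placed < n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("placement failure: geometry too small for ", n_cells,
             " cells at hard-core spacing ", hardcore, " µm", call. = FALSE)
      z <- stats::runif(1, -zmax, zmax)
      ip <- which.min(abs(z_planes - z))
      hz <- sqrt(max(0, 1 - (z_planes[ip] / cc)^2))
      phi <- stats::runif(1, 0, 2 * pi)
      R <- shape_radius(phi, hz, a, b, amps, phases)
      if (R <= margin) next
      rho <- sqrt(stats::runif(1)) * (R - margin)
      x <- rho * cos(phi); y <- rho * sin(phi)
      if (placed > 0L) {
        d2 <- (pts[seq_len(placed), 1] - x)^2 +
          (pts[seq_len(placed), 2] - y)^2 + (pts[seq_len(placed), 3] - z)^2
        if (min(d2) < hardcore^2) next
      }
      placed <- placed + 1L
      pts[placed, ] <- c(x, y, z)
      rfrac[placed] <- rho / R
      plane_idx[placed] <- ip
    }

    ## population assignment: Bernoulli(mix_fraction), optionally radially
    ## biased on the log-odds scale
    p_a <- if (radial_bias == 0) rep(mix_fraction, n_cells) else
      stats::plogis(stats::qlogis(min(max(mix_fraction, 1e-9), 1 - 1e-9)) +
                      radial_bias * (2 * rfrac - 1))
  is_a <- stats::runif(n_cells) < p_a
    population <- ifelse(is_a, "mCherry", "emiRFP")

    ## separable bimodal channel levels (log-normal within population)
    lvl <- function(n, hi) stats::rlnorm(n, meanlog = log(ifelse(hi, 200, 8)),
                                         sdlog = ifelse(hi, 0.25, 0.4))
    mcherry_level <- lvl(n_cells, is_a)
    emirfp_level <- lvl(n_cells, !is_a)

    marker_extreme <- stats::runif(n_cells) < extreme_fraction
    marker_level <- stats::rlnorm(n_cells, log(50), 0.3) *
      ifelse(marker_extreme, 8, 1)

    cells <- data.frame(
      cell_id = seq_len(n_cells),
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      plane = plane_idx,
      population = population,
      mcherry_level = mcherry_level,
      emirfp_level = emirfp_level,
      marker_level = marker_level,
      marker_extreme = marker_extreme,
      radius_frac = rfrac,
      stringsAsFactors = FALSE
    )

    phi_grid <- seq(0, 2 * pi, length.out = gp$n_boundary + 1L)[-(gp$n_boundary + 1L)]
    boundaries <- lapply(z_planes, function(zp) {
      hz <- sqrt(max(0, 1 - (zp / cc)^2))
      R <- shape_radius(phi_grid, hz, a, b, amps, phases)
      cbind(x = R * cos(phi_grid), y = R * sin(phi_grid))
    })
    keep <- vapply(seq_along(z_planes), function(i)
      max(shape_radius(phi_grid, sqrt(max(0, 1 - (z_planes[i] / cc)^2)),
                       a, b, amps, phases)) > margin, logical(1))

    geometry <- gastruloid_geometry(
      centroid = colMeans(pts),
      boundaries = boundaries[keep],
      z_um = z_planes[keep],
      voxel_size = c(1, 1, gp$z_step)
    )

    truth <- list(mix_fraction = mix_fraction,
                  extreme_fraction = extreme_fraction,
                  extreme_ids = cells$cell_id[marker_extreme],
                  radial_bias = radial_bias,
                  density_profile = "uniform",
                  hardcore = hardcore,
                  nucleus_diameter = nucleus_diameter,
                  spillover_slope = NA_real_, plane_offsets = NULL,
                  apoptosis_rates = NULL,
                  geometry_params = gp, seed = seed)

    structure(list(cells = cells, geometry = geometry, truth = truth),
              class = "synthetic_gastruloid")
  })
}

#' @export
print.synthetic_gastruloid <- function(x, ...) {
  tab <- table(x$cells$population)
  cat("Synthetic mosaic gastruloid:", nrow(x$cells), "cells (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("  planes:", length(x$geometry$z_um), " z-range:",
      paste(range(x$geometry$z_um), collapse = "..."), "µm\n")
  cat("  seed:", x$truth$seed, "\n")
  invisible(x)
}

#' Render a synthetic gastruloid into multi-channel voxel stacks
#'
#' Each nucleus is rendered as an anisotropic ellipsoidal blob spanning at
#' least two z-planes. The mCherry and emiRFP channels carry the cell's true
#' (bimodal) levels; the observed marker channel is built per voxel as
#' `true marker + b0(z) + s * B` plus optional Gaussian noise, where `B` is
#' the mCherry (bleed-source) channel. Label masks are emitted per channel
#' and are consistent with the cell table.
#'
#' @param g a `synthetic_gastruloid`.
#' @param voxel_size µm per voxel, length 3 (x, y, z); z must match the
#'   geometry plane spacing.
#' @param nucleus_radii ellipsoid semi-axes of the rendered blob, µm.
#' @param spillover_s spillover slope of the marker injection model.
#' @param plane_offsets per-plane baseline `b0(z)` (recycled to the number of
#'   planes) or a function of z in µm.
#' @param noise_sd additive Gaussian noise s.d. applied to all channels.
#' @param secondary_only if `TRUE`, the true marker contribution is zero
#'   everywhere (a secondary-antibody-only control).
#' @param dims optional fixed voxel grid `c(nx, ny, nz)`; an error is raised
#'   if the geometry does not fit.
#' @param pad padding around the geometry bounding box, µm.
#' @param seed RNG seed for the noise draws.
#' @return list with `channels` (named list of `nx x ny x nz` arrays:
#'   `mcherry`, `emirfp`, `marker`, `marker_true`), `labels` (per-channel
#'   integer label stacks), `z_um`, `origin` (µm of the first voxel centre),
#'   `voxel_size`, and `truth` (injected `s` and `b0`).
#' @export
render_image_stack <- function(g, voxel_size = c(1, 1, 2),
                               nucleus_radii = c(3, 3, 3),
                               spillover_s = 0, plane_offsets = 0,
                               noise_sd = 0, secondary_only = FALSE,
                               dims = NULL, pad = 6, seed = 1L) {
  stopifnot(inherits(g, "synthetic_gastruloid"))
  check_that(all(voxel_size > 0), "voxel spacing must be positive in all axes")
  zs <- g$geometry$z_um
  check_that(isTRUE(all.equal(voxel_size[3], diff(zs)[1])),
             "voxel z-spacing must equal the geometry plane spacing")
  cells <- g$cells
  ext <- apply(cells[, c("x", "y")], 2, range)
  nx_need <- ceiling((diff(ext[, 1]) + 2 * (pad + nucleus_radii[1])) / voxel_size[1])
  ny_need <- ceiling((diff(ext[, 2]) + 2 * (pad + nucleus_radii[2])) / voxel_size[2])
  nz <- length(zs)
  if (is.null(dims)) {
    nx <- nx_need; ny <- ny_need
  } else {
    nx <- dims[1]; ny <- dims[2]
    if (nx < nx_need || ny < ny_need || dims[3] < nz)
      stop("voxel grid ", paste(dims, collapse = "x"),
           " cannot contain the geometry (needs ",
           nx_need, "x", ny_need, "x", nz, ")", call. = FALSE)
    nz <- dims[3]
  }
  origin <- c(ext[1, 1] - pad - nucleus_radii[1] + voxel_size[1] / 2,
              ext[1, 2] - pad - nucleus_radii[2] + voxel_size[2] / 2,
              zs[1])
  z_um <- zs[1] + (seq_len(nz) - 1L) * voxel_size[3]

  b0 <- if (is.function(plane_offsets)) plane_offsets(z_um)
        else rep_len(plane_offsets, nz)

  blank <- array(0, dim = c(nx, ny, nz))
  ch <- list(mcherry = blank, emirfp = blank, marker_true = blank)
  labs <- list(mcherry = array(0L, dim = c(nx, ny, nz)),
               emirfp = array(0L, dim = c(nx, ny, nz)))
  xs <- origin[1] + (seq_len(nx) - 1L) * voxel_size[1]
  ys <- origin[2] + (seq_len(ny) - 1L) * voxel_size[2]

  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]; cy <- cells$y[i]; cz <- cells$z[i]
    ix <- which(abs(xs - cx) <= nucleus_radii[1])
    iy <- which(abs(ys - cy) <= nucleus_radii[2])
    iz <- which(abs(z_um - cz) <= nucleus_radii[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- ((xs[ix] - cx) / nucleus_radii[1])^2
    dy2 <- ((ys[iy] - cy) / nucleus_radii[2])^2
    dz2 <- ((z_um[iz] - cz) / nucleus_radii[3])^2
    inb <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    chan <- if (cells$population[i] == "mCherry") "mcherry" else "emirfp"
    lab <- labs[[chan]][ix, iy, iz, drop = FALSE]
    lab[inb & lab == 0L] <- cells$cell_id[i]
    labs[[chan]][ix, iy, iz] <- lab
  }
  for (chan in c("mcherry", "emirfp")) {
    lvl <- if (chan == "mcherry") cells$mcherry_level else cells$emirfp_level
    idx <- which(labs[[chan]] > 0L)
    ch[[chan]][idx] <- lvl[match(labs[[chan]][idx], cells$cell_id)]
    ## the other population's nuclei still emit their (dim) level in this
    ## channel -- both channels are defined on every nucleus
    other <- setdiff(c("mcherry", "emirfp"), chan)
    idx2 <- which(labs[[other]] > 0L)
    ch[[chan]][idx2] <- lvl[match(labs[[other]][idx2], cells$cell_id)]
  }
  if (!secondary_only) {
    allidx <- which(labs$mcherry > 0L | labs$emirfp > 0L)
    id <- pmax(labs$mcherry[allidx], labs$emirfp[allidx])
    ch$marker_true[allidx] <- cells$marker_level[match(id, cells$cell_id)]
  }

  b0_arr <- array(rep(b0, each = nx * ny), dim = c(nx, ny, nz))
  marker <- ch$marker_true + b0_arr + spillover_s * ch$mcherry
  if (noise_sd > 0) {
    with_seed(seed, {
      n <- length(marker)
      ch$mcherry <- ch$mcherry + stats::rnorm(n, 0, noise_sd)
      ch$emirfp <- ch$emirfp + stats::rnorm(n, 0, noise_sd)
      marker <- ch$marker_true + b0_arr + spillover_s * ch$mcherry +
        stats::rnorm(n, 0, noise_sd)
    })
  }
  list(channels = list(mcherry = ch$mcherry, emirfp = ch$emirfp,
                       marker = marker, marker_true = ch$marker_true),
       labels = labs, z_um = z_um, origin = origin, voxel_size = voxel_size,
       truth = list(spillover_s = spillover_s, b0 = b0, noise_sd = noise_sd,
                    secondary_only = secondary_only))
}

#' Default competition time-course design
#'
#' Study-condition defaults: 150 + 150 seeding for a neutral (WT + WT) mix
#' or 150 + 25 when a supercompetitor population is present, 24-h sampling to
#' 120 h, winner growth rate ln(2)/10 per hour, and a competition gate from
#' 48 to 96 h inside which the loser's net growth drops to `stagnation_rate`.
#'
#' @param competition logical; stagnate the loser inside the gate?
#' @param seeding named integer vector of seeded cells per population.
#' @param times sampling times in hours.
#' @param rates named per-population net growth rates, per hour.
#' @param gate two-element numeric, start and end of the gate (hours).
#' @param stagnation_rate loser net growth rate inside the gate, per hour.
#' @param loser name of the loser population.
#' @param n_gastruloids replicate gastruloids.
#' @param noise `"poisson"` or `"none"`.
#' @param condition condition label stored in the output.
#' @return a design list for [generate_count_timecourse()].
#' @export
count_design <- function(competition = TRUE,
                         seeding = if (competition) c(mCherry = 150, emiRFP = 25)
                                   else c(mCherry = 150, emiRFP = 150),
                         times = seq(0, 120, by = 24),
                         rates = c(mCherry = log(2) / 10, emiRFP = log(2) / 10),
                         gate = c(48, 96),
                         stagnation_rate = log(2) / 10 - log(1 / 0.3) / diff(gate),
                         loser = "mCherry",
                         n_gastruloids = 12,
                         noise = "poisson",
                         condition = if (competition) "WT+KO" else "WT+WT") {
  list(competition = competition, seeding = seeding, times = times,
       rates = rates, gate = gate, stagnation_rate = stagnation_rate,
       loser = loser, n_gastruloids = n_gastruloids, noise = noise,
       condition = condition)
}

## Net growth exposure of a population from 0 to t under a design.
growth_exposure <- function(t, rate, gated, gate, stag) {
  if (!gated) return(rate * t)
  t_in <- pmax(0, pmin(t, gate[2]) - gate[1])
  rate * (t - t_in) + stag * t_in
}

#' Generate a per-gastruloid competition count time course
#'
#' Counts grow near-exponentially from the seeded numbers; when competition
#' is enabled the loser population's net growth is set to the stagnation
#' rate inside the gate interval. Replicate noise is Poisson by default.
#'
#' @param design a design list from [count_design()].
#' @param seed integer RNG seed.
#' @return a long-format data frame (class `count_table`) with columns
#'   `gastruloid_id`, `condition`, `time_h`, `population`, `count`, plus
#'   attributes `seeding` and `design`.
#' @export
generate_count_timecourse <- function(design = count_design(), seed = 1L) {
  d <- design
  check_that(length(d$seeding) >= 1 && all(d$seeding >= 0),
             "design must specify nonnegative seeding numbers")
  check_that(length(d$times) >= 1, "design must specify time points")
  check_that(all(d$rates >= 0), "negative growth rates are not supported")
  pops <- names(d$seeding)
  grid <- expand.grid(gastruloid_id = seq_len(d$n_gastruloids),
                      time_h = d$times, population = pops,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- mapply(function(tp, pop) {
    gated <- isTRUE(d$competition) && pop == d$loser
    d$seeding[[pop]] * exp(growth_exposure(tp, d$rates[[pop]], gated,
                                           d$gate, d$stagnation_rate))
  }, grid$time_h, grid$population)
  counts <- with_seed(seed, {
    if (identical(d$noise, "poisson")) stats::rpois(length(mu), mu)
    else as.integer(round(mu))
  })
  out <- data.frame(gastruloid_id = paste0(d$condition, "_g",
                                           grid$gastruloid_id),
                    condition = d$condition, time_h = grid$time_h,
                    population = grid$population, count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "seeding") <- d$seeding
  attr(out, "design") <- d
  class(out) <- c("count_table", "data.frame")
  out
}

#' Generate annotated apoptotic events for a synthetic gastruloid
#'
#' Samples events among the gastruloid's cells, assigns a ground-truth stage
#' with stage-consistent morphology flags, Casp3 mean intensities elevated in
#' late events, reduced areas for late events, and dim channel intensities
#' inherited from the owning cell. Optionally mixes in small low-Casp3 debris
#' objects, and optionally biases event locations towards locally dense
#' regions.
#'
#' @param g a `synthetic_gastruloid`.
#' @param n_events number of true apoptotic events.
#' @param stage_probs probabilities for stages early/mid/late.
#' @param n_debris number of debris objects to add.
#' @param density_bias nonnegative power; event cells are sampled with
#'   probability proportional to local density to this power (0 = uniform).
#' @param seed RNG seed.
#' @return data frame of events with morphology flags, `casp3_mean`, `area`,
#'   channel means, truth columns `stage_true`, `is_debris`,
#'   `population_true`.
#' @export
generate_apoptosis_events <- function(g, n_events = 60,
                                      stage_probs = c(early = 0.4, mid = 0.25,
                                                      late = 0.35),
                                      n_debris = 20, density_bias = 0,
                                      seed = 1L) {
  stopifnot(inherits(g, "synthetic_gastruloid"))
  cells <- g$cells
  check_that(n_events <= nrow(cells), "more events than cells")
  with_seed(seed, {
    w <- rep(1, nrow(cells))
    if (density_bias > 0) {
      rho <- local_density(cells[, c("x", "y", "z")],
                           n = min(10L, nrow(cells) - 1L), exclusion = 0)
      w <- (rho / stats::median(rho))^density_bias
    }
    ids <- sample(cells$cell_id, n_events, prob = w)
    stage <- sample(c("early", "mid", "late"), n_events, replace = TRUE,
                    prob = stage_probs / sum(stage_probs))
    flags <- data.frame(
      nucleus_intact = stage == "early",
      membrane_disintegrated = stage == "mid",
      chromatin_granules = stage == "mid",
      chromatin_compacted = stage == "late",
      reduced_size = stage == "late",
      casp3_pattern = ifelse(stage == "early", "cytoplasmic", "nuclear"),
      stringsAsFactors = FALSE
    )
    casp3 <- stats::rlnorm(n_events,
                           meanlog = log(ifelse(stage == "late", 300, 100)),
                           sdlog = 0.3)
    area <- ifelse(stage == "late",
                   stats::rnorm(n_events, 25, 4),
                   stats::rnorm(n_events, 60, 8))
    ci <- match(ids, cells$cell_id)
    ev <- data.frame(event_id = seq_len(n_events), cell_id = ids,
                     x = cells$x[ci], y = cells$y[ci], z = cells$z[ci],
                     stage_true = stage, is_debris = FALSE,
                     casp3_mean = casp3, area = pmax(area, 5),
                     mcherry_mean = cells$mcherry_level[ci] * 0.6,
                     emirfp_mean = cells$emirfp_level[ci] * 0.6,
                     population_true = cells$population[ci],
                     stringsAsFactors = FALSE)
    ev <- cbind(ev, flags)
    if (n_debris > 0) {
      db_ci <- sample(nrow(cells), n_debris)
      db <- data.frame(event_id = n_events + seq_len(n_debris),
                       cell_id = NA_integer_,
                       x = cells$x[db_ci] + stats::rnorm(n_debris, 0, 2),
                       y = cells$y[db_ci] + stats::rnorm(n_debris, 0, 2),
                       z = cells$z[db_ci],
                       stage_true = "late", is_debris = TRUE,
                       casp3_mean = stats::rlnorm(n_debris, log(60), 0.4),
                       area = pmax(stats::rnorm(n_debris, 6, 2), 1),
                       mcherry_mean = stats::rlnorm(n_debris, log(5), 0.4),
                       emirfp_mean = stats::rlnorm(n_debris, log(5), 0.4),
                       population_true = NA_character_,
                       stringsAsFactors = FALSE)
      db$nucleus_intact <- FALSE; db$membrane_disintegrated <- FALSE
      db$chromatin_granules <- FALSE; db$chromatin_compacted <- TRUE
      db$reduced_size <- TRUE; db$casp3_pattern <- "nuclear"
      ev <- rbind(ev, db[, names(ev)])
    }
    ev
  })
}

#' Generate a stage-labelled reference pseudobulk with known-truth queries
#'
#' Stage centroids lie on a smooth trajectory in log-expression space; query
#' samples are generated at known stages with multiplicative log-normal
#' noise. Anterior and posterior endpoint profiles and mixture queries with
#' known mixing coefficients are included for gradient-embedding tests.
#'
#' @param n_genes number of genes (>= 10).
#' @param stages stage labels (>= 2) or a stage count.
#' @param noise_sd s.d. of the log-scale query noise (0 = exact centroids).
#' @param alphas mixing coefficients of the posterior endpoint for the
#'   mixture queries.
#' @param seed RNG seed.
#' @return list with `reference` (genes x stages), `queries` (one per
#'   stage), `query_truth`, `anterior`, `posterior`, `mixture_queries`,
#'   `alpha_truth`, `seed`.
#' @export
generate_reference_pseudobulk <- function(n_genes = 400, stages = 6,
                                          noise_sd = 0.1,
                                          alphas = c(0.2, 0.5, 0.8),
                                          seed = 1L) {
  if (length(stages) == 1 && is.numeric(stages))
    stages <- sprintf("stage%02d", seq_len(stages))
  check_that(length(stages) >= 2, "need at least 2 stages")
  check_that(n_genes >= 10, "need at least 10 genes")
  with_seed(seed, {
    S <- length(stages)
    tau <- seq(0, 1, length.out = S)
    a <- stats::rnorm(n_genes, 3, 1)
    b <- stats::rnorm(n_genes, 0, 1.5)
    cs <- stats::rnorm(n_genes, 0, 1)
    ph <- stats::runif(n_genes, 0, pi)
    logexpr <- function(t) a + b %o% t + cs * sin(outer(ph, t * pi, `+`))
    reference <- exp(logexpr(tau))
    dimnames(reference) <- list(sprintf("gene%04d", seq_len(n_genes)), stages)
    queries <- exp(logexpr(tau) + stats::rnorm(n_genes * S, 0, noise_sd))
    dimnames(queries) <- list(rownames(reference),
                              paste0("query_", stages))
    anterior <- reference[, 1]
    posterior <- reference[, S]
    mix <- sapply(alphas, function(al) {
      m <- al * posterior + (1 - al) * anterior
      m * exp(stats::rnorm(n_genes, 0, noise_sd))
    })
    colnames(mix) <- sprintf("mix_a%03.0f", alphas * 100)
    list(reference = reference, stage_labels = stages,
         queries = queries, query_truth = stages,
         anterior = anterior, posterior = posterior,
         mixture_queries = mix, alpha_truth = alphas, seed = seed)
  })
}

#' Write a rendered stack and its ground truth to disk
#'
#' Channels go to one multi-page TIFF per channel (plane-major order), label
#' masks to 16-bit TIFFs, the cell table to CSV, and the ground truth to
#' JSON (requires jsonlite). The generator seed travels in the JSON.
#'
#' @param g a `synthetic_gastruloid`.
#' @param stack a rendered stack from [render_image_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_stack <- function(g, stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  sc <- max(1, max(vapply(stack$channels, max, numeric(1))))
  for (nm in names(stack$channels)) {
    f <- file.path(dir, paste0("channel_", nm, ".tif"))
    pl <- lapply(seq_len(dim(stack$channels[[nm]])[3]), function(k)
      pmin(pmax(stack$channels[[nm]][, , k] / sc, 0), 1))
    tiff::writeTIFF(pl, f, bits.per.sample = 16L)
    files <- c(files, f)
  }
  for (nm in names(stack$labels)) {
    f <- file.path(dir, paste0("labels_", nm, ".tif"))
    pl <- lapply(seq_len(dim(stack$labels[[nm]])[3]), function(k)
      stack$labels[[nm]][, , k] / 65535)
    tiff::writeTIFF(pl, f, bits.per.sample = 16L)
    files <- c(files, f)
  }
  f <- file.path(dir, "cells.csv")
  utils::write.csv(g$cells, f, row.names = FALSE)
  files <- c(files, f)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    f <- file.path(dir, "truth.json")
    jsonlite::write_json(list(seed = g$truth$seed,
                              mix_fraction = g$truth$mix_fraction,
                              extreme_fraction = g$truth$extreme_fraction,
                              spillover_s = stack$truth$spillover_s,
                              b0 = stack$truth$b0,
                              intensity_scale = sc),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
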