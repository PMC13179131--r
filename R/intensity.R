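## Marker quantification chain: spillover calibration on secondary-only
## controls, per-plane baseline estimation, per-pixel correction, per-cell
## nuclear means, per-plane Tukey-fence gating of extreme-high cells,
## population disambiguation, and the nuclear/cytoplasmic ratio.

#' Fit the global spillover slope on a secondary-only control stack
#'
#' On in-cell pixels of a control where the true marker signal is absent,
#' the observed marker channel follows `C_sec(z) = b0(z) + s * B(z)` with
#' `B` the bleed-source channel. The slope `s` is estimated by pooled
#' ordinary least squares with per-plane intercepts absorbed (within-plane
#' centering), and is treated as global for the imaging session.
#'
#' @param marker observed marker array (`nx x ny x nz`).
#' @param bleed bleed-source channel array, same dimensions.
#' @param mask logical array of in-cell pixels (e.g. the union of nuclear
#'   label masks).
#' @return list of class `spillover_fit`: `s`, `se`, `r_squared`,
#'   `n_pixels`.
#' @export
fit_spillover <- function(marker, bleed, mask) {
  stopifnot(identical(dim(marker), dim(bleed)),
            identical(dim(marker), dim(mask)))
  nz <- dim(marker)[3]
  xs <- ys <- vector("list", nz)
  for (z in seq_len(nz)) {
    m <- mask[, , z]
    if (!any(m)) next
    x <- bleed[, , z][m]; y <- marker[, , z][m]
    xs[[z]] <- x - mean(x); ys[[z]] <- y - mean(y)
  }
  x <- unlist(xs); y <- unlist(ys)
  check_that(length(x) > 2, "control masks are empty")
  sxx <- sum(x^2)
  if (sxx == 0)
    stop("bleed-source channel has zero variance within cells; ",
         "spillover slope is unidentifiable", call. = FALSE)
  s <- sum(x * y) / sxx
  res <- y - s * x
  dof <- length(x) - 1 - sum(vapply(xs, function(v) length(v) > 0, logical(1)))
  se <- sqrt(sum(res^2) / max(dof, 1) / sxx)
  r2 <- if (sum(y^2) == 0) 1 else 1 - sum(res^2) / sum(y^2)
  structure(list(s = s, se = se, r_squared = r2, n_pixels = length(x)),
            class = "spillover_fit")
}

#' @export
print.spillover_fit <- function(x, ...) {
  cat(sprintf("Spillover slope s = %.5f (s.e. %.2g, R² %.3f, %d pixels)\n",
              x$s, x$se, x$r_squared, x$n_pixels))
  invisible(x)
}

#' Estimate per-plane baseline offsets
#'
#' `b0(z)` is the median of the residuals `C_obs(z) - s * B(z)` over in-cell
#' pixels at each z -- a robust per-plane baseline. Planes with no in-cell
#' pixels are filled by linear interpolation from neighbouring planes and
#' flagged.
#'
#' @param marker,bleed,mask as in [fit_spillover()].
#' @param s spillover slope.
#' @return numeric vector `b0` per plane, with attribute `interpolated`
#'   (logical per plane).
#' @export
estimate_plane_offsets <- function(marker, bleed, mask, s) {
  stopifnot(identical(dim(marker), dim(bleed)))
  nz <- dim(marker)[3]
  b0 <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    m <- mask[, , z]
    if (any(m)) b0[z] <- stats::median(marker[, , z][m] - s * bleed[, , z][m])
  }
  interp <- is.na(b0)
  if (all(interp))
    stop("no plane has in-cell pixels; cannot estimate offsets", call. = FALSE)
  if (any(interp)) {
    ok <- which(!interp)
    b0 <- stats::approx(ok, b0[ok], xout = seq_len(nz), rule = 2)$y
  }
  structure(b0, interpolated = interp)
}

#' Assemble a spillover model
#'
#' @param s global spillover slope (a number or a `spillover_fit`).
#' @param b0 per-plane offsets.
#' @param z_um optional physical z per plane.
#' @return object of class `spillover_model`.
#' @export
spillover_model <- function(s, b0, z_um = NULL) {
  fit <- NULL
  if (inherits(s, "spillover_fit")) { fit <- s; s <- fit$s }
  check_that(is.finite(s), "s must be finite")
  structure(list(s = s, b0 = as.numeric(b0), z_um = z_um, fit = fit),
            class = "spillover_model")
}

#' @export
print.spillover_model <- function(x, ...) {
  cat(sprintf("Spillover model: s = %.5f, %d plane offsets (range %.3g..%.3g)\n",
              x$s, length(x$b0), min(x$b0), max(x$b0)))
  invisible(x)
}

#' @export
coef.spillover_model <- function(object, ...) {
  c(s = object$s, stats::setNames(object$b0,
                                  paste0("b0_", seq_along(object$b0))))
}

#' Predict the no-signal (secondary-only) marker level
#'
#' @param object a `spillover_model`.
#' @param bleed bleed-source array.
#' @param ... unused.
#' @return array `b0(z) + s * B`.
#' @export
predict.spillover_model <- function(object, bleed, ...) {
  dm <- dim(bleed)
  check_that(dm[3] == length(object$b0), "model planes do not cover stack")
  b0_arr <- array(rep(object$b0, each = dm[1] * dm[2]), dim = dm)
  b0_arr + object$s * bleed
}

#' Apply the per-pixel spillover correction
#'
#' `C_corr(z) = C_obs(z) - b0(z) - s * B(z)`. Corrected values may be
#' negative by design: clipping at zero would bias the per-plane medians the
#' model relies on.
#'
#' @param marker observed marker array.
#' @param bleed bleed-source array.
#' @param model a [spillover_model()].
#' @return corrected array.
#' @export
correct_channel <- function(marker, bleed, model) {
  stopifnot(inherits(model, "spillover_model"))
  check_that(identical(dim(marker), dim(bleed)), "shape mismatch")
  marker - predict(model, bleed)
}

#' Mean corrected intensity within a nuclear mask
#'
#' @param stack corrected intensity array (or matrix).
#' @param mask logical array of the same shape.
#' @return arithmetic mean over mask pixels.
#' @export
nuclear_mean <- function(stack, mask) {
  check_that(identical(dim(stack), dim(mask)), "shape mismatch")
  check_that(any(mask), "empty nuclear mask")
  mean(stack[mask])
}

#' Per-cell mean corrected intensity from a label stack
#'
#' @param stack corrected intensity array.
#' @param labels integer label array of the same shape.
#' @return named numeric vector of means, one per label id.
#' @export
nuclear_means <- function(stack, labels) {
  check_that(identical(dim(stack), dim(labels)), "shape mismatch")
  idx <- which(labels > 0L)
  check_that(length(idx) > 0, "no labelled pixels")
  tapply(stack[idx], labels[idx], mean)
}

#' Per-plane Tukey-fence gating of extreme-high marker cells
#'
#' For each plane z the fence is `tau_z = Q3_z + multiplier * IQR_z`
#' (quartiles by linear interpolation, the type-7 rule); a cell is flagged
#' extreme-high when its value strictly exceeds the fence of its plane.
#' Planes with fewer than `min_per_plane` cells are merged with the nearest
#' preceding plane (or following, for the first) and flagged.
#'
#' @param values per-cell marker means.
#' @param plane per-cell plane index.
#' @param multiplier fence multiplier (default 4.5).
#' @param min_per_plane minimum cells required to compute quartiles.
#' @return list with `high` (logical per cell) and `fences` (per plane:
#'   `Q1`, `Q3`, `IQR`, `tau`, `merged_into`).
#' @export
classify_extreme_high <- function(values, plane, multiplier = 4.5,
                                  min_per_plane = 4L) {
  check_that(length(values) == length(plane), "values/plane length mismatch")
  planes <- sort(unique(plane))
  group <- stats::setNames(planes, planes)   # plane -> group representative
  counts <- table(factor(plane, levels = planes))
  repeat {
    gtab <- tapply(as.numeric(counts), group[as.character(planes)], sum)
    small <- names(gtab)[gtab < min_per_plane]
    if (!length(small) || length(gtab) == 1L) break
    g <- small[1]
    members <- planes[group[as.character(planes)] == g]
    others <- setdiff(unique(group), g)
    tgt <- others[which.min(abs(as.numeric(others) - as.numeric(g)))]
    group[as.character(members)] <- tgt
  }
  gid <- group[as.character(plane)]
  fences <- do.call(rbind, lapply(unique(group), function(g) {
    v <- values[gid == g]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(group = g, Q1 = q[1], Q3 = q[2], IQR = q[2] - q[1],
               tau = q[2] + multiplier * (q[2] - q[1]))
  }))
  per_plane <- data.frame(plane = planes,
                          merged_into = unname(group[as.character(planes)]))
  per_plane <- merge(per_plane, fences, by.x = "merged_into", by.y = "group")
  per_plane <- per_plane[order(per_plane$plane),
                         c("plane", "Q1", "Q3", "IQR", "tau", "merged_into")]
  tau_of <- stats::setNames(per_plane$tau, per_plane$plane)
  high <- values > tau_of[as.character(plane)]
  list(high = unname(high), fences = per_plane, multiplier = multiplier)
}

#' Disambiguate populations by 2-cluster partitioning of channel intensities
#'
#' Cells segmented in both fluorescence channels are resolved by k-means
#' (k = 2) on the two channel means, with deterministic farthest-pair
#' initialisation. The cluster with the higher mean in the mCherry channel
#' is identified as the mCherry population (and symmetrically for emiRFP);
#' cells whose recorded segmentation channel disagrees with their cluster
#' are excluded with a flag.
#'
#' @param intensities two-column matrix (`mcherry`, `emirfp` channel means).
#' @param seg_channel recorded segmentation population per cell
#'   (`"mCherry"`/`"emiRFP"`).
#' @return list: `population` (cluster-derived label), `excluded` (logical),
#'   `centers` (2 x 2 cluster means).
#' @export
assign_population <- function(intensities, seg_channel) {
  X <- as.matrix(intensities)
  check_that(nrow(X) >= 2, "need at least two cells")
  if (all(apply(X, 2, function(v) diff(range(v)) == 0)))
    stop("all cells have identical intensities; clusters collapse",
         call. = FALSE)
  ## deterministic farthest-pair initialisation
  D <- as.matrix(stats::dist(X))
  w <- arrayInd(which.max(D), dim(D))
  init <- X[c(w[1], w[2]), , drop = FALSE]
  km <- stats::kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd")
  ctr <- km$centers
  mch_cluster <- which.max(ctr[, 1])
  lab <- ifelse(km$cluster == mch_cluster, "mCherry", "emiRFP")
  excluded <- !is.na(seg_channel) & lab != seg_channel
  list(population = lab, excluded = excluded, centers = ctr)
}

#' Nuclear-to-cytoplasmic ratio with compartment-wise background subtraction
#'
#' The cytoplasmic mask is the membrane mask minus the nuclear region.
#' Backgrounds (from secondary-antibody-only samples) are subtracted
#' independently per compartment before the ratio is taken. A non-positive
#' cytoplasmic denominator yields `NA` with a flag.
#'
#' @param channel intensity matrix/array (e.g. YAP).
#' @param nuclear_mask,membrane_mask logical masks of the same shape.
#' @param nuclear_bg,cyto_bg compartment backgrounds.
#' @return list: `ratio`, `nuclear_mean`, `cyto_mean`, `flagged`.
#' @export
yap_nc_ratio <- function(channel, nuclear_mask, membrane_mask,
                         nuclear_bg = 0, cyto_bg = 0) {
  cyto_mask <- membrane_mask & !nuclear_mask
  check_that(any(nuclear_mask), "empty nuclear compartment")
  check_that(any(cyto_mask), "empty cytoplasmic compartment")
  nm <- mean(channel[nuclear_mask]) - nuclear_bg
  cm <- mean(channel[cyto_mask]) - cyto_bg
  if (cm <= 0)
    return(list(ratio = NA_real_, nuclear_mean = nm, cyto_mean = cm,
                flagged = TRUE))
  list(ratio = nm / cm, nuclear_mean = nm, cyto_mean = cm, flagged = FALSE)
}
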