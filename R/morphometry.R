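## Whole-gastruloid 2D shape pipeline: summed channels, Gaussian blur,
## maximum-entropy thresholding, particle filtering, area and aspect ratio.

#' Kapur maximum-entropy threshold
#'
#' Exhaustive search over histogram levels for the threshold maximising the
#' sum of foreground and background Shannon entropies of the normalised
#' intensity histogram.
#'
#' @param image numeric matrix.
#' @param n_bins histogram bins (default 256).
#' @return threshold intensity; pixels strictly above it are foreground.
#'   Attribute `bin` gives the selected bin index.
#' @export
max_entropy_threshold <- function(image, n_bins = 256L) {
  rng <- range(image)
  if (diff(rng) == 0)
    stop("constant image: no threshold exists", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(image, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- h / sum(h)
  P <- cumsum(p)
  ent <- function(q) ifelse(q > 0, -q * log(q), 0)
  cum_e <- cumsum(ent(p))
  tot_e <- cum_e[n_bins]
  best <- -Inf; best_t <- 1L
  for (t in seq_len(n_bins - 1L)) {
    Pb <- P[t]
    if (Pb <= 0 || Pb >= 1) next
    Hb <- cum_e[t] / Pb + log(Pb)
    Hf <- (tot_e - cum_e[t]) / (1 - Pb) + log(1 - Pb)
    if (Hb + Hf > best) { best <- Hb + Hf; best_t <- t }
  }
  structure(breaks[best_t + 1L], bin = best_t)
}

#' Whole-gastruloid 2D shape from fluorescence channels
#'
#' Channels are summed; a Gaussian blur (sigma 0.6 px) is applied; the
#' blurred image is binarised at the maximum-entropy threshold; connected
#' components below `min_px` pixels are discarded as artefacts; holes in the
#' surviving region are filled; the area and the second-moment fitted
#' ellipse aspect ratio of the largest kept component are measured.
#'
#' @param channels list of intensity matrices (at least one), or a single
#'   matrix.
#' @param sigma Gaussian blur sigma in pixels.
#' @param min_px particle-filter minimum component size, pixels.
#' @param n_bins histogram bins for the threshold.
#' @param pixel_size µm per pixel (for the area in µm²).
#' @return object of class `shape_result`: `area_px`, `area_um2`,
#'   `aspect_ratio` (major/minor, >= 1), `n_objects_kept`, `threshold`.
#' @export
gastruloid_shape <- function(channels, sigma = 0.6, min_px = 5000L,
                             n_bins = 256L, pixel_size = 1) {
  if (is.matrix(channels)) channels <- list(channels)
  check_that(length(channels) >= 1, "need at least one channel")
  img <- Reduce(`+`, channels)
  blurred <- as.matrix(EBImage::gblur(img, sigma = sigma))
  thr <- max_entropy_threshold(blurred, n_bins)
  mask <- (blurred > thr) * 1
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  if (!length(keep))
    stop("no object of at least ", min_px, " pixels found", call. = FALSE)
  big <- keep[which.max(sizes[keep])]
  obj <- EBImage::fillHull((lab == big) * 1)
  pix <- which(obj > 0, arr.ind = TRUE)
  area_px <- nrow(pix)
  cv <- stats::cov(pix) * (area_px - 1) / area_px + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE)$values
  structure(list(area_px = area_px, area_um2 = area_px * pixel_size^2,
                 aspect_ratio = sqrt(ev[1] / ev[2]),
                 n_objects_kept = length(keep),
                 threshold = as.numeric(thr)),
            class = "shape_result")
}

#' @export
print.shape_result <- function(x, ...) {
  cat(sprintf(
    "Gastruloid shape: area %d px (%.0f µm²), aspect ratio %.2f (%d object%s kept)\n",
    x$area_px, x$area_um2, x$aspect_ratio, x$n_objects_kept,
    if (x$n_objects_kept == 1) "" else "s"))
  invisible(x)
}
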