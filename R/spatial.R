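## Spatial statistics on validated cell tables: relative radial position,
## local cell density, and neighbourhood composition.

#' Construct a gastruloid geometry
#'
#' The reference frame for radial statistics: a 3D centroid plus per-plane
#' closed boundary polygons in µm.
#'
#' @param centroid numeric length 3, µm.
#' @param boundaries list of two-column vertex matrices (µm), one per plane,
#'   closed implicitly.
#' @param z_um physical z of each plane, µm.
#' @param voxel_size µm per axis, length 3.
#' @return object of class `gastruloid_geometry`.
#' @export
gastruloid_geometry <- function(centroid, boundaries, z_um,
                                voxel_size = c(1, 1, 2)) {
  check_that(length(centroid) == 3, "centroid must be (x, y, z)")
  check_that(length(boundaries) == length(z_um),
             "one boundary polygon per plane required")
  for (p in boundaries) {
    check_that(is.matrix(p) && ncol(p) == 2 && nrow(p) >= 3,
               "each boundary must be a closed polygon with >= 3 vertices")
    check_that(!anyDuplicated(p), "boundary polygon has duplicated vertices")
  }
  structure(list(centroid = as.numeric(centroid), boundaries = boundaries,
                 z_um = as.numeric(z_um),
                 voxel_size = as.numeric(voxel_size)),
            class = "gastruloid_geometry")
}

#' @export
print.gastruloid_geometry <- function(x, ...) {
  cat("Gastruloid geometry:", length(x$z_um), "planes, centroid (",
      paste(signif(x$centroid, 4), collapse = ", "), ") µm\n")
  invisible(x)
}

#' Build a geometry from a validated cell table
#'
#' The centroid is the unweighted mean of the cell centres. Boundaries are
#' taken from `boundaries`/`z_um` if supplied, otherwise detected per plane
#' from `stack_planes` with [detect_plane_boundary()].
#'
#' @param cells data frame with columns `x`, `y`, `z` (µm).
#' @param boundaries,z_um optional precomputed per-plane polygons.
#' @param stack_planes optional named list: `planes` (list of image
#'   matrices), `z_um`, `pixel_size`, `origin` -- input to boundary
#'   detection.
#' @param ... passed on to [detect_plane_boundary()].
#' @return a `gastruloid_geometry`.
#' @export
geometry_from_cells <- function(cells, boundaries = NULL, z_um = NULL,
                                stack_planes = NULL, ...) {
  centroid <- colMeans(cells[, c("x", "y", "z")])
  if (is.null(boundaries)) {
    check_that(!is.null(stack_planes), "need boundaries or stack_planes")
    z_um <- stack_planes$z_um
    boundaries <- lapply(stack_planes$planes, detect_plane_boundary,
                         pixel_size = stack_planes$pixel_size %||% c(1, 1),
                         origin = stack_planes$origin %||% c(0, 0), ...)
  }
  gastruloid_geometry(centroid, boundaries, z_um)
}

#' Extract the outer boundary of one z-plane by morphological Chan--Vese
#'
#' Region-based active contour without edges: the binary level set is
#' evolved by switching boundary pixels to whichever region mean (`c1`
#' inside, `c2` outside) they are closer to in squared intensity, followed
#' by a morphological curvature-smoothing step (closing then opening), until
#' the set stabilises. The outer contour of the largest foreground component
#' is returned as a closed polygon in µm.
#'
#' @param plane numeric image matrix (first dimension = x).
#' @param pixel_size µm per pixel, length-2 (x, y) or scalar.
#' @param origin µm coordinate of the first pixel centre.
#' @param max_iter iteration cap.
#' @param smoothing number of morphological smoothing passes per iteration.
#' @return two-column vertex matrix (µm) with attributes `iterations` and
#'   `area_um2`. Non-convergence raises a condition of class
#'   `gastrucomp_cv_nonconvergence` carrying the last contour in
#'   `$contour`.
#' @export
detect_plane_boundary <- function(plane, pixel_size = c(1, 1),
                                  origin = c(0, 0), max_iter = 200L,
                                  smoothing = 1L) {
  pixel_size <- rep_len(pixel_size, 2)
  rng <- range(plane)
  if (diff(rng) == 0)
    stop("plane contains no contrast (constant image); no boundary exists",
         call. = FALSE)
  u <- (plane > mean(rng)) * 1
  if (sum(u) == 0) u <- (plane > stats::quantile(plane, 0.75)) * 1
  brush <- EBImage::makeBrush(3, shape = "box")
  prev <- NULL; prev2 <- NULL
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    inside <- u > 0
    c1 <- mean(plane[inside]); c2 <- mean(plane[!inside])
    if (is.nan(c1) || is.nan(c2)) break
    dil <- EBImage::dilate(u, brush); ero <- EBImage::erode(u, brush)
    band <- (dil - ero) > 0
    closer_in <- (plane - c1)^2 < (plane - c2)^2
    u[band & closer_in] <- 1
    u[band & !closer_in] <- 0
    for (s in seq_len(smoothing)) {
      u <- EBImage::erode(EBImage::dilate(u, brush), brush)   # closing
      u <- EBImage::dilate(EBImage::erode(u, brush), brush)   # opening
    }
    if (!is.null(prev) && (identical(u, prev) || identical(u, prev2))) {
      converged <- TRUE
      break
    }
    prev2 <- prev; prev <- u
  }
  if (sum(u) == 0)
    stop("Chan-Vese level set vanished; no foreground found", call. = FALSE)
  lab <- EBImage::bwlabel(u)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  oc <- EBImage::ocontour(EBImage::Image((lab == big) * 1))[[1]]
  poly <- cbind(x = origin[1] + oc[, 1] * pixel_size[1],
                y = origin[2] + oc[, 2] * pixel_size[2])
  poly <- poly[!duplicated(poly), , drop = FALSE]
  ## the traced polygon runs through boundary-pixel centres; push each
  ## vertex half a pixel along the outward normal so the contour follows
  ## the pixel outer edge
  if (nrow(poly) >= 3) {
    n <- nrow(poly)
    nxt <- poly[c(2:n, 1), ]; prv <- poly[c(n, 1:(n - 1)), ]
    tang <- nxt - prv
    len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
    nrm <- cbind(tang[, 2], -tang[, 1]) / len
    ctr <- colMeans(poly)
    flip <- rowSums(nrm * sweep(poly, 2, ctr)) < 0
    nrm[flip, ] <- -nrm[flip, ]
    poly <- poly + 0.5 * mean(pixel_size) * nrm
  }
  if (!converged) {
    cond <- structure(
      class = c("gastrucomp_cv_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "Chan-Vese did not converge within %d iterations", max_iter),
        call = sys.call(-1), contour = poly))
    stop(cond)
  }
  structure(poly, iterations = iters, area_um2 = polygon_area(poly))
}

#' Relative radial position of cells in a gastruloid
#'
#' For each cell, `P = Dc / (Dc + De)` where `Dc` is the 3D Euclidean
#' distance to the gastruloid centroid and `De` the 3D distance to the
#' nearest boundary point over all planes (boundary polygons are densified
#' to at most `max_edge` µm edges first). `P` is 0 at the centroid and 1 on
#' the boundary. A centre falling outside its plane's boundary is assigned
#' `P = 1` and flagged.
#'
#' @param centres data frame or matrix with columns `x`, `y`, `z` (µm).
#' @param geometry a [gastruloid_geometry].
#' @param max_edge boundary densification edge length, µm.
#' @return data frame with columns `P`, `Dc`, `De`, `outside`.
#' @export
radial_position <- function(centres, geometry, max_edge = 1) {
  stopifnot(inherits(geometry, "gastruloid_geometry"))
  centres <- as.data.frame(centres)
  dense <- lapply(geometry$boundaries, densify_polygon, max_edge = max_edge)
  verts <- do.call(rbind, lapply(seq_along(dense), function(i)
    cbind(dense[[i]], geometry$z_um[i])))
  ctr <- geometry$centroid
  n <- nrow(centres)
  P <- Dc <- De <- numeric(n)
  outside <- logical(n)
  for (i in seq_len(n)) {
    p <- c(centres$x[i], centres$y[i], centres$z[i])
    Dc[i] <- sqrt(sum((p - ctr)^2))
    De[i] <- sqrt(min((verts[, 1] - p[1])^2 + (verts[, 2] - p[2])^2 +
                        (verts[, 3] - p[3])^2))
    ip <- which.min(abs(geometry$z_um - p[3]))
    inb <- point_in_polygon(p[1], p[2], geometry$boundaries[[ip]])
    if (!inb && De[i] > 1e-9) {
      outside[i] <- TRUE
      P[i] <- 1
    } else {
      P[i] <- if (Dc[i] + De[i] == 0) 0 else Dc[i] / (Dc[i] + De[i])
    }
  }
  data.frame(P = P, Dc = Dc, De = De, outside = outside)
}

## All-pairs Euclidean distances between rows of a coordinate matrix.
coord_dist <- function(coords) {
  as.matrix(stats::dist(coords))
}

#' Local cell density from k-nearest neighbours
#'
#' The inverse cubic mean distance to the `n` nearest neighbours in 3D:
#' `rho = (mean(d^3))^-1`, in µm^-3. Neighbours closer than
#' `exclusion * diameter` of the focal cell are removed before selecting the
#' `n` nearest (an anti-artefact guard against doubly-segmented nuclei).
#'
#' @param coords matrix/data frame of cell centres, columns `x`, `y`, `z`
#'   (µm).
#' @param n number of neighbours.
#' @param exclusion exclusion radius as a fraction of the focal cell
#'   diameter.
#' @param diameter focal cell diameter(s), µm: scalar or per-cell vector.
#'   Required when `exclusion > 0`. The equivalent-circle diameter
#'   `2*sqrt(area/pi)` of the centre-plane area is the usual choice.
#' @param candidates optional logical vector marking cells eligible as
#'   neighbours (e.g. to exclude apoptotic cells); focal cells are always
#'   all rows.
#' @return numeric vector of densities, µm^-3.
#' @export
local_density <- function(coords, n = 20, exclusion = 0.25, diameter = NULL,
                          candidates = NULL) {
  X <- as.matrix(as.data.frame(coords)[, c("x", "y", "z")])
  N <- nrow(X)
  check_that(N >= 2, "need at least two cells")
  if (exclusion > 0) {
    check_that(!is.null(diameter),
               "diameter is required when exclusion > 0")
    diameter <- rep_len(diameter, N)
  }
  cand <- candidates %||% rep(TRUE, N)
  D <- coord_dist(X)
  rho <- numeric(N)
  for (i in seq_len(N)) {
    d <- D[i, ]
    keep <- cand
    keep[i] <- FALSE
    if (exclusion > 0) keep <- keep & (d >= exclusion * diameter[i])
    d <- d[keep]
    if (length(d) < n)
      stop(sprintf(
        "cell %d has only %d eligible neighbours (< n = %d) after exclusion",
        i, length(d), n), call. = FALSE)
    dn <- sort(d, partial = n)[seq_len(n)]
    rho[i] <- 1 / mean(dn^3)
  }
  rho
}

#' Neighbourhood composition over the k nearest neighbours
#'
#' For each cell, the fraction of its `k` nearest neighbours (3D Euclidean)
#' belonging to each population, and the same fractions normalised by the
#' gastruloid-wide population fractions (1 = neighbourhood mirrors the
#' global mix).
#'
#' @param coords cell centres (columns `x`, `y`, `z`, µm).
#' @param populations population label per cell.
#' @param k neighbours per cell (default 20).
#' @param candidates optional logical vector of neighbour eligibility.
#' @return data frame with `fraction_<pop>` and `normalized_<pop>` columns.
#' @export
neighbourhood_composition <- function(coords, populations, k = 20,
                                      candidates = NULL) {
  X <- as.matrix(as.data.frame(coords)[, c("x", "y", "z")])
  N <- nrow(X)
  populations <- as.character(populations)
  cand <- candidates %||% rep(TRUE, N)
  check_that(sum(cand) - 1 >= k,
             sprintf("fewer than k = %d eligible neighbours", k))
  pops <- sort(unique(populations))
  glob <- as.numeric(table(factor(populations, levels = pops))) / N
  D <- coord_dist(X)
  frac <- matrix(0, N, length(pops), dimnames = list(NULL, pops))
  for (i in seq_len(N)) {
    d <- D[i, ]
    keep <- cand; keep[i] <- FALSE
    idx <- which(keep)
    nb <- idx[order(d[idx])[seq_len(k)]]
    tab <- table(factor(populations[nb], levels = pops))
    frac[i, ] <- as.numeric(tab) / k
  }
  norm <- sweep(frac, 2, glob, `/`)
  out <- data.frame(frac, norm)
  names(out) <- c(paste0("fraction_", pops), paste0("normalized_", pops))
  out
}

#' Append spatial metrics to a cell table
#'
#' Convenience wrapper computing `P`, `rho_local` and neighbourhood
#' composition for every cell of one gastruloid.
#'
#' @param cells cell table with `x`, `y`, `z` and optionally
#'   `centre_area` (µm², for the density exclusion rule) and `population`.
#' @param geometry a [gastruloid_geometry].
#' @param k,n,exclusion metric parameters (see [local_density()],
#'   [neighbourhood_composition()]).
#' @return `cells` with metric columns appended.
#' @export
spatial_metrics <- function(cells, geometry, k = 20, n = 20,
                            exclusion = 0.25) {
  rp <- radial_position(cells, geometry)
  cells$P <- rp$P
  cells$outside_boundary <- rp$outside
  diam <- if ("centre_area" %in% names(cells))
    2 * sqrt(cells$centre_area / pi) else NULL
  cells$rho_local <- local_density(cells, n = n,
                                   exclusion = if (is.null(diam)) 0 else exclusion,
                                   diameter = diam)
  if ("population" %in% names(cells))
    cells <- cbind(cells,
                   neighbourhood_composition(cells, cells$population, k = k))
  cells
}
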