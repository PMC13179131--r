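## Validation of 3D segmented objects: centre-plane selection, centroids,
## data-driven size thresholds, and the object-validity filter.

#' Construct a labeled object (a candidate cell before validation)
#'
#' A candidate cell as it comes out of plane-wise segmentation: per-plane
#' pixel coordinates (µm), areas and per-channel summed intensities, indexed
#' by strictly increasing plane indices.
#'
#' @param id object id (matches the label value in the masks).
#' @param channel segmentation channel name.
#' @param z_index integer plane indices, strictly increasing.
#' @param z_um physical z of each plane, µm.
#' @param pix list of two-column matrices of pixel-centre coordinates (µm),
#'   one per plane.
#' @param sums numeric matrix, planes x channels, of summed intensities
#'   within the mask (named columns).
#' @param pixel_area area of one pixel, µm².
#' @return object of class `labeled_object`.
#' @export
labeled_object <- function(id, channel, z_index, z_um, pix, sums,
                           pixel_area = 1) {
  check_that(length(z_index) >= 1, "object must have at least one plane")
  check_that(all(diff(z_index) > 0), "plane indices must be strictly increasing")
  npix <- vapply(pix, nrow, integer(1))
  check_that(all(npix > 0), "empty plane mask")
  structure(list(id = id, channel = channel,
                 z_index = as.integer(z_index), z_um = as.numeric(z_um),
                 pix = pix, npix = npix, area = npix * pixel_area,
                 sums = sums, pixel_area = pixel_area),
            class = "labeled_object")
}

#' @export
print.labeled_object <- function(x, ...) {
  cat("Labeled object", x$id, "(", x$channel, "):",
      length(x$z_index), "planes, areas",
      paste(signif(x$area, 3), collapse = "/"), "µm²\n")
  invisible(x)
}

#' Extract labeled objects from a label stack
#'
#' Objects are identified by label value; the same label id on different
#' planes belongs to the same object (the stitching rule of the upstream
#' segmentation).
#'
#' @param labels integer label array `nx x ny x nz`.
#' @param channels named list of intensity arrays with matching dimensions.
#' @param channel name recorded as the object's segmentation channel.
#' @param z_um physical z per plane.
#' @param voxel_size µm per voxel (x, y, z).
#' @param origin µm of the first voxel centre (x, y).
#' @return list of `labeled_object`s.
#' @export
extract_objects <- function(labels, channels, channel, z_um,
                            voxel_size = c(1, 1, 2), origin = c(0, 0)) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(list())
  dm <- dim(labels)
  arr <- arrayInd(idx, dm)
  lab <- labels[idx]
  xm <- origin[1] + (arr[, 1] - 1L) * voxel_size[1]
  ym <- origin[2] + (arr[, 2] - 1L) * voxel_size[2]
  pixel_area <- voxel_size[1] * voxel_size[2]
  key <- paste(lab, arr[, 3], sep = ":")
  chsum_list <- lapply(channels, function(ch) rowsum(ch[idx], key))
  chsum <- do.call(cbind, chsum_list)
  colnames(chsum) <- names(channels)
  rownames(chsum) <- rownames(chsum_list[[1]])
  keys <- sort(unique(key))
  split_idx <- split(seq_along(idx), key)
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  key_lab <- as.integer(parts[, 1]); key_z <- as.integer(parts[, 2])
  out <- lapply(sort(unique(key_lab)), function(id) {
    sel <- which(key_lab == id)
    sel <- sel[order(key_z[sel])]
    zi <- key_z[sel]
    pix <- lapply(sel, function(s) {
      rows <- split_idx[[keys[s]]]
      cbind(x = xm[rows], y = ym[rows])
    })
    sums <- chsum[keys[sel], , drop = FALSE]
    rownames(sums) <- NULL
    labeled_object(id, channel, zi, z_um[zi], pix, sums, pixel_area)
  })
  out
}

#' Centre plane of a labeled object
#'
#' The z-plane with the highest summed fluorescence intensity within the
#' mask. Ties resolve to the lower plane index.
#'
#' @param obj a `labeled_object`.
#' @param channel channel used for the intensity sum; defaults to the
#'   object's own segmentation channel.
#' @return the plane index (value of `z_index`), with the within-object
#'   position as attribute `which`.
#' @export
find_centre_plane <- function(obj, channel = obj$channel) {
  stopifnot(inherits(obj, "labeled_object"))
  check_that(length(obj$z_index) >= 1, "empty object")
  s <- obj$sums[, channel]
  w <- which.max(s)                      # first max = lower plane on ties
  structure(obj$z_index[w], which = w)
}

#' 3D cell centre of a labeled object
#'
#' x, y are the area centroid of the centre-plane mask (mean of pixel-centre
#' coordinates); z is the physical z of the centre plane.
#'
#' @param obj a `labeled_object`.
#' @param centre_plane plane index from [find_centre_plane()]; computed if
#'   missing.
#' @param channel channel for centre-plane selection.
#' @return named numeric `(x, y, z)` in µm.
#' @export
cell_centre <- function(obj, centre_plane = NULL, channel = obj$channel) {
  stopifnot(inherits(obj, "labeled_object"))
  if (is.null(centre_plane)) centre_plane <- find_centre_plane(obj, channel)
  w <- match(centre_plane, obj$z_index)
  check_that(!is.na(w), "centre_plane is not a plane of this object")
  check_that(obj$npix[w] > 0, "empty centre-plane mask")
  xy <- colMeans(obj$pix[[w]])
  c(x = unname(xy[1]), y = unname(xy[2]), z = obj$z_um[w])
}

#' Data-driven minimum-area threshold by KDE bandwidth scanning
#'
#' Fits a Gaussian kernel density estimate to the centre-plane area
#' distribution at each bandwidth of an ascending grid and returns the
#' interior local-minimum location of the first (smallest) bandwidth whose
#' density has exactly one interior local minimum -- the debris/cell
#' separation point. Interior excludes the evaluation-domain endpoints.
#'
#' @param areas centre-plane areas, µm² (>= 20 values).
#' @param bandwidth_grid ascending bandwidths, µm²; default a geometric
#'   sequence from 0.5 to 20 in 40 steps.
#' @param n_grid KDE evaluation points, spanning the 0.5th to 99.5th
#'   percentile of the areas.
#' @param stability the single-minimum configuration must persist over this
#'   factor of bandwidths above the selected one (mode persistence); noise
#'   wiggles of unimodal samples pass through a single-minimum state only
#'   fleetingly as the bandwidth grows, and this guard keeps them from
#'   masquerading as a debris/cell separation.
#' @param max_area upper size threshold stored alongside (µm²).
#' @return object of class `area_threshold` with `min_area`, `max_area`,
#'   `bandwidth_used` and `kde` (the selected density curve). If no
#'   bandwidth yields exactly one interior minimum, an error of class
#'   `gastrucomp_no_threshold` is raised.
#' @export
estimate_min_area_threshold <- function(areas,
                                        bandwidth_grid =
                                          exp(seq(log(0.5), log(20),
                                                  length.out = 40)),
                                        n_grid = 512, stability = 2.5,
                                        max_area = 200) {
  check_that(length(areas) >= 20, "need at least 20 area values")
  check_that(all(diff(bandwidth_grid) > 0), "bandwidth grid must ascend")
  ## symmetric percentile trimming keeps the evaluation domain (and hence
  ## the selected bandwidth) translation-equivariant
  hi <- stats::quantile(areas, 0.995, names = FALSE)
  lo <- stats::quantile(areas, 0.005, names = FALSE)
  interior_minima <- function(bw) {
    d <- stats::density(areas, bw = bw, n = n_grid, from = lo, to = hi)
    s <- sign(diff(d$y))
    s[s == 0] <- 1
    mins <- which(diff(s) > 0) + 1L          # indices into y, interior only
    list(d = d, mins = mins[mins > 1L & mins < n_grid])
  }
  n_mins <- vapply(bandwidth_grid,
                   function(bw) length(interior_minima(bw)$mins), integer(1))
  for (i in which(n_mins == 1L)) {
    persist <- bandwidth_grid >= bandwidth_grid[i] &
      bandwidth_grid <= stability * bandwidth_grid[i]
    if (!all(n_mins[persist] == 1L)) next
    im <- interior_minima(bandwidth_grid[i])
    thr <- im$d$x[im$mins]
    return(structure(list(min_area = thr, max_area = max_area,
                          bandwidth_used = bandwidth_grid[i],
                          kde = data.frame(area = im$d$x,
                                           density = im$d$y)),
                     class = "area_threshold"))
  }
  cond <- structure(
    class = c("gastrucomp_no_threshold", "error", "condition"),
    list(message = paste("no bandwidth in the grid yields exactly one",
                         "interior local minimum; area distribution is not",
                         "separably bimodal"),
         call = sys.call(-1)))
  stop(cond)
}

#' @export
print.area_threshold <- function(x, ...) {
  cat(sprintf(
    "Area threshold: keep %.2f-%.0f µm² (KDE bandwidth %.2f µm²)\n",
    x$min_area, x$max_area, x$bandwidth_used))
  invisible(x)
}

#' Validate labeled objects into cell records
#'
#' Applies the object-validity criteria: (1) presence in at least two
#' consecutive z-planes and (2) centre-plane area within
#' `[min_area, max_area]` (the upper bound defaults to 200 µm²). Survivors
#' become one cell record each, with per-channel means computed on the
#' centre plane only (crosstalk minimisation); rejections are logged with a
#' reason code.
#'
#' @param objects list of `labeled_object`s.
#' @param thr an `area_threshold` (or a list with `min_area`, `max_area`).
#' @param gastruloid_id id recorded on every cell.
#' @param channel channel for centre-plane selection; default each object's
#'   own segmentation channel.
#' @return list with `cells` (data frame: id, centre, centre plane/area,
#'   per-channel means, population = segmentation channel) and `rejections`
#'   (object id + reason: `non_consecutive`, `too_small`, `too_large`).
#' @export
filter_valid_cells <- function(objects, thr, gastruloid_id = "g1",
                               channel = NULL) {
  check_that(is.numeric(thr$min_area) && is.numeric(thr$max_area) &&
               thr$min_area > 0 && thr$min_area < thr$max_area,
             "invalid area thresholds (need 0 < min_area < max_area)")
  cells <- list(); rej <- list()
  for (obj in objects) {
    ch <- channel %||% obj$channel
    consec <- length(obj$z_index) >= 2 && any(diff(obj$z_index) == 1L)
    cp <- find_centre_plane(obj, ch)
    w <- attr(cp, "which")
    ca <- obj$area[w]
    reason <- if (!consec) "non_consecutive"
      else if (ca < thr$min_area) "too_small"
      else if (ca > thr$max_area) "too_large"
      else NA_character_
    if (is.na(reason)) {
      ctr <- cell_centre(obj, cp, ch)
      means <- obj$sums[w, ] / obj$npix[w]
      rec <- data.frame(cell_id = obj$id, gastruloid_id = gastruloid_id,
                        x = ctr[["x"]], y = ctr[["y"]], z = ctr[["z"]],
                        centre_plane = as.integer(cp), centre_area = ca,
                        population = if (obj$channel == "mcherry") "mCherry"
                                     else if (obj$channel == "emirfp") "emiRFP"
                                     else obj$channel,
                        stringsAsFactors = FALSE)
      for (nm in colnames(obj$sums)) rec[[paste0(nm, "_mean")]] <- means[[nm]]
      cells[[length(cells) + 1L]] <- rec
    } else {
      rej[[length(rej) + 1L]] <- data.frame(object_id = obj$id,
                                            reason = reason,
                                            centre_area = ca,
                                            stringsAsFactors = FALSE)
    }
  }
  list(cells = if (length(cells)) do.call(rbind, cells) else
         data.frame(cell_id = integer(0)),
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(object_id = integer(0), reason = character(0)))
}
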