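test_that("centre plane maximises summed intensity (brute-force check)", {
  # single plane -> that plane
  o1 <- labeled_object(1, "ch1", 5L, 10, list(cbind(x = 1, y = 1)),
                       matrix(3, 1, 1, dimnames = list(NULL, "ch1")))
  expect_equal(as.integer(find_centre_plane(o1)), 5L)

  # sums (10, 50, 20) -> middle plane
  o2 <- labeled_object(2, "ch1", 1:3, (1:3) * 2,
                       replicate(3, cbind(x = 1, y = 1), simplify = FALSE),
                       matrix(c(10, 50, 20), 3, 1,
                              dimnames = list(NULL, "ch1")))
  expect_equal(as.integer(find_centre_plane(o2)), 2L)

  # ties resolve to the lower plane index
  o3 <- labeled_object(3, "ch1", 1:3, (1:3) * 2,
                       replicate(3, cbind(x = 1, y = 1), simplify = FALSE),
                       matrix(c(10, 50, 50), 3, 1,
                              dimnames = list(NULL, "ch1")))
  expect_equal(as.integer(find_centre_plane(o3)), 2L)

  set.seed(21)
  for (i in 1:100) {
    obj <- random_object(i)
    cp <- find_centre_plane(obj, "ch2")
    expect_equal(as.integer(cp),
                 obj$z_index[which.max(obj$sums[, "ch2"])])
  }
})

test_that("cell centre equals the mean of mask pixel coordinates", {
  # square mask centred at (10, 10)
  sq <- as.matrix(expand.grid(x = 8.5:11.5, y = 8.5:11.5))
  o <- labeled_object(1, "ch1", 4L, 8, list(sq),
                      matrix(1, 1, 1, dimnames = list(NULL, "ch1")))
  expect_equal(cell_centre(o), c(x = 10, y = 10, z = 8))

  # L-shaped mask: brute-force pixel average
  L <- rbind(as.matrix(expand.grid(x = 0.5:4.5, y = 0.5)),
             as.matrix(expand.grid(x = 0.5, y = 1.5:6.5)))
  oL <- labeled_object(2, "ch1", 2L, 4, list(L),
                       matrix(1, 1, 1, dimnames = list(NULL, "ch1")))
  ctr <- cell_centre(oL)
  expect_equal(ctr[["x"]], mean(L[, 1]))
  expect_equal(ctr[["y"]], mean(L[, 2]))
  # centroid inside the bounding box
  expect_true(ctr[["x"]] >= min(L[, 1]) && ctr[["x"]] <= max(L[, 1]))
})

test_that("KDE area threshold: bimodal separation, translation equivariance, unimodal error", {
  set.seed(2)
  areas <- c(rnorm(600, 8, 2), rnorm(1400, 60, 10))
  thr <- estimate_min_area_threshold(areas)
  expect_s3_class(thr, "area_threshold")
  # threshold separates the two modes
  expect_gt(thr$min_area, 12)
  expect_lt(thr$min_area, 40)

  # shifting all areas shifts the threshold by the same amount
  thr_shift <- estimate_min_area_threshold(areas + 100)
  expect_equal(thr_shift$min_area, thr$min_area + 100, tolerance = 0.02)
  expect_equal(thr_shift$bandwidth_used, thr$bandwidth_used)

  set.seed(3)
  expect_error(estimate_min_area_threshold(rnorm(500, 60, 10)),
               class = "gastrucomp_no_threshold")
})

test_that("validity filter matches brute-force predicates and conserves objects", {
  set.seed(31)
  objects <- lapply(1:500, random_object)
  thr <- list(min_area = 31.75, max_area = 200)
  fv <- filter_valid_cells(objects, thr)

  expect_equal(nrow(fv$cells) + nrow(fv$rejections), 500)
  expect_length(intersect(fv$cells$cell_id, fv$rejections$object_id), 0)

  keep_oracle <- vapply(objects, function(o) {
    consec <- length(o$z_index) >= 2 && any(diff(o$z_index) == 1)
    ca <- o$area[which.max(o$sums[, "ch1"])]
    consec && ca >= 31.75 && ca <= 200
  }, logical(1))
  expect_setequal(fv$cells$cell_id, which(keep_oracle))

  # named rejection reasons are faithful
  nc <- fv$rejections$reason == "non_consecutive"
  for (id in fv$rejections$object_id[nc]) {
    o <- objects[[id]]
    expect_false(length(o$z_index) >= 2 && any(diff(o$z_index) == 1))
  }

  # raising min_area never grows the accepted set
  fv2 <- filter_valid_cells(objects, list(min_area = 60, max_area = 200))
  expect_true(all(fv2$cells$cell_id %in% fv$cells$cell_id))
})

test_that("explicit criterion examples behave as defined", {
  mk <- function(zi, area_side) {
    pix <- lapply(zi, function(z) as.matrix(
      expand.grid(x = (seq_len(area_side)) - 0.5,
                  y = (seq_len(area_side)) - 0.5)))
    labeled_object(1, "ch1", zi, zi * 2, pix,
                   matrix(seq_along(zi), length(zi), 1,
                          dimnames = list(NULL, "ch1")))
  }
  thr <- list(min_area = 31.75, max_area = 200)
  # planes {3,5}: non-consecutive -> rejected
  r <- filter_valid_cells(list(mk(c(3L, 5L), 12)), thr)
  expect_equal(nrow(r$cells), 0)
  expect_equal(r$rejections$reason, "non_consecutive")
  # planes {3,4}, centre area 144 µm² -> accepted
  a <- filter_valid_cells(list(mk(c(3L, 4L), 12)), thr)
  expect_equal(nrow(a$cells), 1)
  expect_equal(a$cells$centre_area, 144)
})

test_that("objects extracted from label stacks reproduce ground-truth centres", {
  g <- generate_point_gastruloid(300, 0.5, seed = 5)
  st <- render_image_stack(g, nucleus_radii = c(3, 3, 3), noise_sd = 0)
  objs <- c(
    extract_objects(st$labels$mcherry, st$channels[c("mcherry", "emirfp")],
                    "mcherry", st$z_um, st$voxel_size, st$origin),
    extract_objects(st$labels$emirfp, st$channels[c("mcherry", "emirfp")],
                    "emirfp", st$z_um, st$voxel_size, st$origin))
  fv <- filter_valid_cells(objs, list(min_area = 15, max_area = 200))
  m <- merge(fv$cells, g$cells, by = "cell_id")
  expect_gte(nrow(m), 0.99 * nrow(g$cells))
  ok <- abs(m$x.x - m$x.y) <= st$voxel_size[1] &
    abs(m$y.x - m$y.y) <= st$voxel_size[2] &
    abs(m$z.x - m$z.y) <= st$voxel_size[3]
  expect_gte(mean(ok), 0.99)
  expect_equal(m$population.x, m$population.y)
})
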