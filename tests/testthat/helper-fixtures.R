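# Fixtures built in code: spherical geometries, disk/ellipse images, and
# random labeled objects.

# Spherical geometry of radius R with per-plane circular boundaries whose
# vertex grids include the angle 0 (so points on the +x axis coincide with a
# vertex exactly).
sphere_geometry <- function(R = 50, z_step = 2, n_vertices = 720,
                            centroid = c(0, 0, 0)) {
  zmax <- floor((R * 0.999) / z_step) * z_step
  zs <- seq(-zmax, zmax, by = z_step)
  ph <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  bnd <- lapply(zs, function(z) {
    r <- sqrt(R^2 - z^2)
    cbind(x = centroid[1] + r * cos(ph), y = centroid[2] + r * sin(ph))
  })
  gastruloid_geometry(centroid, bnd, zs + centroid[3])
}

# Binary disk image: pixel centres at (i - 0.5), value `fg` inside radius.
disk_image <- function(n = 100, radius = 40, centre = n / 2, fg = 1) {
  xc <- (seq_len(n)) - 0.5
  d2 <- outer((xc - centre)^2, (xc - centre)^2, `+`)
  (d2 <= radius^2) * fg
}

# High-contrast ellipse image (full axes a, b pixels) with background level
# and Gaussian noise, emulating a widefield fluorescence field of view.
ellipse_image <- function(n = 300, a = 200, b = 100, fg = 100, bg = 20,
                          noise_sd = 4, angle = 0) {
  xc <- (seq_len(n)) - 0.5 - n / 2
  X <- matrix(xc, n, n); Y <- matrix(xc, n, n, byrow = TRUE)
  if (angle != 0) {
    Xr <- cos(angle) * X + sin(angle) * Y
    Yr <- -sin(angle) * X + cos(angle) * Y
    X <- Xr; Y <- Yr
  }
  img <- ((X / (a / 2))^2 + (Y / (b / 2))^2 <= 1) * fg
  img + matrix(stats::rnorm(n * n, bg, noise_sd), n, n)
}

# Random labeled object: random plane set (possibly non-consecutive), random
# per-plane rectangular masks and intensity sums.
random_object <- function(id, pixel_size = 1, channels = c("ch1", "ch2")) {
  nplanes <- sample(1:4, 1)
  zi <- sort(sample(1:10, nplanes))
  pix <- lapply(seq_len(nplanes), function(i) {
    w <- sample(3:15, 1); h <- sample(3:15, 1)
    x0 <- runif(1, 0, 50); y0 <- runif(1, 0, 50)
    as.matrix(expand.grid(x = x0 + (seq_len(w) - 0.5) * pixel_size,
                          y = y0 + (seq_len(h) - 0.5) * pixel_size))
  })
  sums <- matrix(runif(nplanes * length(channels), 10, 1000),
                 nplanes, length(channels), dimnames = list(NULL, channels))
  labeled_object(id, channels[1], zi, zi * 2, pix, sums,
                 pixel_area = pixel_size^2)
}

# Small rendered mosaic used by several intensity tests.
small_render <- function(seed = 2, s = 0.05, noise_sd = 0,
                         secondary_only = TRUE,
                         offsets = function(z) 10 + 0.5 * (z - min(z))) {
  g <- generate_point_gastruloid(
    200, 0.5, geometry_params = list(semi_axes = c(26, 24, 18)),
    nucleus_diameter = 4, seed = seed)
  st <- render_image_stack(g, nucleus_radii = c(2, 2, 2.5), spillover_s = s,
                           plane_offsets = offsets, noise_sd = noise_sd,
                           secondary_only = secondary_only,
                           dims = c(64, 64, 20), seed = seed + 1)
  list(g = g, st = st,
       mask = st$labels$mcherry > 0 | st$labels$emirfp > 0)
}
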