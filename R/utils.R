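## Internal geometry and numeric helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test whether points lie inside a closed polygon
#'
#' Even-odd (ray casting) rule. Points exactly on an edge may fall on either
#' side; callers that care use a margin.
#'
#' @param x,y point coordinates (recycled together).
#' @param poly two-column matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    i <- k; jj <- j[k]
    crosses <- ((py[i] > y) != (py[jj] > y)) &
      (x < (px[jj] - px[i]) * (y - py[i]) / (py[jj] - py[i]) + px[i])
    inside <- xor(inside, crosses)
  }
  inside
}

#' Densify a closed polygon so no edge exceeds a maximum length
#'
#' Vertices are interpolated along each edge (including the closing edge);
#' original vertices are retained, which bounds the discretisation error of
#' nearest-vertex distance queries by `max_edge`/2.
#'
#' @param poly two-column matrix of vertices.
#' @param max_edge maximum allowed edge length, same units as `poly`.
#' @return two-column matrix of the densified polygon.
#' @keywords internal
densify_polygon <- function(poly, max_edge = 1) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3, max_edge > 0)
  n <- nrow(poly)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / max_edge))
    t <- seq(0, 1, length.out = nseg + 1L)[-(nseg + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

## Shoelace area of a closed polygon (absolute value).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (0.5 -> 1), unlike base
#' [round()]'s round-half-even. Used for reporting percentages.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## stopifnot with a readable message
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
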