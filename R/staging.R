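## Transcriptome comparison utilities: median-ratio normalisation with
## log1p, Euclidean staging against timed references, and the
## anterior-posterior mixture-gradient embedding.

#' Median-ratio normalisation followed by log1p
#'
#' Size factor per sample = median, over genes with nonzero counts in all
#' samples, of the ratio of the sample's count to the gene's geometric mean
#' across samples. Counts are divided by the size factor and
#' log1p-transformed.
#'
#' @param counts nonnegative genes x samples matrix (>= 2 samples).
#' @return list: `normalized` (log1p scale), `size_factors`.
#' @export
median_ratio_normalize <- function(counts) {
  counts <- as.matrix(counts)
  check_that(ncol(counts) >= 2, "need at least 2 samples")
  check_that(all(counts >= 0), "counts must be nonnegative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has nonzero counts in all samples; size factors are",
         " undefined", call. = FALSE)
  loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - loggeo)))
  normalized <- log1p(sweep(counts, 2, sf, `/`))
  list(normalized = normalized, size_factors = sf)
}

## Top highly-variable genes of a reference matrix (by variance).
select_hvg <- function(reference, n_hvg) {
  v <- apply(reference, 1, stats::var)
  rownames(reference)[order(v, decreasing = TRUE)[seq_len(min(n_hvg,
                                                              nrow(reference)))]]
}

#' Euclidean staging of query transcriptomes against timed references
#'
#' Pairwise Euclidean distances on the shared gene space (optionally
#' restricted to the reference's most variable genes), plus the nearest
#' reference stage per query. Both sides must be normalised identically
#' beforehand.
#'
#' @param queries genes x query-samples matrix.
#' @param references genes x reference-samples matrix, column names = stage
#'   labels.
#' @param n_hvg optionally restrict to this many highly-variable reference
#'   genes.
#' @return list: `distances` (queries x references), `nearest_stage`.
#' @export
stage_distance <- function(queries, references, n_hvg = NULL) {
  queries <- as.matrix(queries); references <- as.matrix(references)
  shared <- intersect(rownames(queries), rownames(references))
  check_that(length(shared) > 0, "no shared genes between query and reference")
  if (!is.null(n_hvg))
    shared <- intersect(shared, select_hvg(references[shared, , drop = FALSE],
                                           n_hvg))
  q <- queries[shared, , drop = FALSE]
  r <- references[shared, , drop = FALSE]
  D <- matrix(0, ncol(q), ncol(r),
              dimnames = list(colnames(queries), colnames(references)))
  for (j in seq_len(ncol(q)))
    D[j, ] <- sqrt(colSums((r - q[, j])^2))
  list(distances = D,
       nearest_stage = colnames(r)[apply(D, 1, which.min)])
}

#' Position a query on an anterior-posterior mixture gradient
#'
#' Mixtures `m(alpha) = alpha * posterior + (1 - alpha) * anterior` are
#' built over a grid of proportions; mixtures and query are projected onto
#' the leading principal axis of the mixture set, and the grid alpha whose
#' projection is nearest the query's is returned.
#'
#' @param query expression vector (or genes x samples matrix) on the same
#'   genes and normalisation as the references.
#' @param anterior,posterior endpoint reference profiles.
#' @param grid mixture proportions in `[0, 1]` (default 0, 0.1, ..., 1).
#' @return numeric alpha per query sample, with the projections as
#'   attribute `projection`.
#' @export
ap_gradient_position <- function(query, anterior, posterior,
                                 grid = seq(0, 1, by = 0.1)) {
  check_that(all(grid >= 0 & grid <= 1), "grid must lie in [0, 1]")
  if (identical(as.numeric(anterior), as.numeric(posterior)))
    stop("anterior and posterior references are identical; the gradient is",
         " degenerate", call. = FALSE)
  q <- as.matrix(query)
  mix <- sapply(grid, function(al) al * posterior + (1 - al) * anterior)
  pc <- stats::prcomp(t(mix), center = TRUE, scale. = FALSE, rank. = 1)
  proj_mix <- pc$x[, 1]
  proj_q <- scale(t(q), center = pc$center, scale = FALSE) %*%
    pc$rotation[, 1, drop = FALSE]
  alpha <- grid[apply(abs(outer(as.numeric(proj_q), proj_mix, `-`)), 1,
                      which.min)]
  structure(alpha, projection = as.numeric(proj_q))
}
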