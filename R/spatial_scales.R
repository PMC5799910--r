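#' Great-circle distance matrix
#'
#' Haversine distances between sample coordinates, Earth radius 6371.0 km.
#'
#' @param meta metadata with `longitude`/`latitude` in decimal degrees.
#' @return symmetric matrix of distances in km, samples in metadata order.
#' @export
geodesic_matrix <- function(meta) {
  meta <- validate_sample_metadata(meta)
  bad <- !is.finite(meta$longitude) | !is.finite(meta$latitude)
  if (any(bad))
    stop("missing coordinates for: ", paste(meta$sample_id[bad], collapse = ", "))
  xy <- cbind(meta$longitude, meta$latitude)
  G <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(G) <- list(meta$sample_id, meta$sample_id)
  G
}

#' PCNM spatial eigenfunctions
#'
#' Principal Coordinates of Neighbour Matrices: distances beyond the
#' truncation threshold are replaced by four times the threshold, the
#' resulting matrix is double-centred (`-d^2/2`) and eigendecomposed, and
#' the axes with positive eigenvalues (eigenvalue > 1e-8 of the largest)
#' are returned as unit-norm, mutually orthogonal spatial predictors sorted
#' from broadest to finest scale. The automatic threshold is the longest
#' edge of the minimum spanning tree of the distances, which keeps all
#' points connected. Computation is delegated to [vegan::pcnm()].
#'
#' @param G geographic distance matrix (km) or `dist` object.
#' @param truncation truncation distance in km, or `NULL` for the minimum
#'   spanning tree default.
#' @return object of class `pcnm_basis`: list with `values` (descending
#'   positive eigenvalues), `vectors` (samples x axes, unit norm) and
#'   `threshold`.
#' @export
pcnm_axes <- function(G, truncation = NULL) {
  G <- as.matrix(G)
  if (nrow(G) < 3L) stop("PCNM needs at least 3 samples")
  if (all(G[upper.tri(G)] == 0)) stop("all points identical; no positive axes")
  p <- if (is.null(truncation)) vegan::pcnm(stats::as.dist(G))
       else vegan::pcnm(stats::as.dist(G), threshold = truncation)
  if (is.null(p$vectors) || ncol(p$vectors) == 0)
    stop("no positive PCNM eigenvalues")
  vals <- p$values[seq_len(ncol(p$vectors))]
  keep <- vals > 1e-8 * max(vals)
  vec <- p$vectors[, keep, drop = FALSE]
  rownames(vec) <- rownames(G)
  structure(list(values = vals[keep], vectors = vec,
                 threshold = p$threshold),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat("PCNM basis:", length(x$values), "positive axes, truncation",
      signif(x$threshold, 5), "km\n")
  invisible(x)
}

#' Assign sample pairs to equal-width distance bins
#'
#' Pairwise distances are partitioned into `n_bins` equal-width, left-closed
#' intervals spanning the observed range (the last interval is closed on
#' both sides). With `from_zero = TRUE` the range starts at 0 instead of the
#' minimum observed pair distance. Sixteen bins mirror the spatial-scale
#' resolution used in large-transect soil surveys.
#'
#' @param G geographic distance matrix (km).
#' @param n_bins number of bins, default 16.
#' @param from_zero start the binned range at zero rather than the minimum
#'   observed pair distance.
#' @return object of class `pair_bins`: list with `pairs` (data.frame `i`,
#'   `j`, `distance`, `bin`), `centers`, `breaks`, `n_bins`.
#' @export
bin_pairs <- function(G, n_bins = 16L, from_zero = FALSE) {
  G <- as.matrix(G)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_bins == 1L) warning("single bin: all pairs pooled")
  idx <- which(upper.tri(G), arr.ind = TRUE)
  d <- G[idx]
  lo <- if (from_zero) 0 else min(d)
  hi <- max(d)
  if (lo == hi) stop("all pair distances identical; cannot bin")
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  if (length(unique(d)) < n_bins)
    warning("fewer distinct distances than bins; empty bins possible")
  pairs <- data.frame(i = idx[, 1], j = idx[, 2], distance = d, bin = bin)
  structure(list(pairs = pairs,
                 centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 breaks = breaks, n_bins = as.integer(n_bins),
                 sample_ids = rownames(G)),
            class = "pair_bins")
}

#' Per-scale process contribution table
#'
#' For each distance bin: pair count, median betaNTI, and the percentage of
#' classifiable pairs assigned to deterministic (`|betaNTI| > 2`) versus
#' stochastic assembly. The two percentages sum to exactly 100
#' (`stochastic_pct` is computed as the complement). Bins are labelled
#' small/medium/large by the `bands` thresholds; the defaults (250 km and
#' 800 km) follow the narrative grouping of continental-transect soil
#' studies, where a jump to determinism appears beyond roughly 800 km.
#'
#' @param B `beta_nti` object (computed on the same samples as `bins`).
#' @param bins `pair_bins` from [bin_pairs()].
#' @param bands length-2 increasing km thresholds separating small/medium
#'   and medium/large scales.
#' @param threshold betaNTI classification threshold, default 2.
#' @return data.frame (class `scale_table`): `scale`, `distance_km`,
#'   `n_pairs`, `median_bnti`, `deterministic_pct`, `stochastic_pct`,
#'   `band`. Empty bins keep `n_pairs = 0` and `NA` statistics.
#' @export
scale_table <- function(B, bins, bands = c(250, 800), threshold = 2) {
  stopifnot(inherits(B, "beta_nti"), inherits(bins, "pair_bins"))
  if (!identical(bins$sample_ids, B$sample_ids))
    stop("bins and betaNTI computed on different sample sets")
  v <- B$beta_nti[cbind(bins$pairs$i, bins$pairs$j)]
  out <- data.frame(scale = seq_len(bins$n_bins),
                    distance_km = bins$centers,
                    n_pairs = 0L, median_bnti = NA_real_,
                    deterministic_pct = NA_real_, stochastic_pct = NA_real_)
  for (b in seq_len(bins$n_bins)) {
    inb <- bins$pairs$bin == b
    out$n_pairs[b] <- sum(inb)
    vb <- v[inb & is.finite(v)]
    if (!length(vb)) next
    out$median_bnti[b] <- median(vb)
    det <- 100 * sum(abs(vb) > threshold) / length(vb)
    out$deterministic_pct[b] <- det
    out$stochastic_pct[b] <- 100 - det
  }
  out$band <- cut(out$distance_km, c(-Inf, bands, Inf),
                  labels = c("small", "medium", "large"))
  class(out) <- c("scale_table", "data.frame")
  out
}

#' Kruskal-Wallis test of betaNTI across distance bins
#'
#' Rank-based test (with tie correction, chi-square reference distribution)
#' of whether the betaNTI distribution differs among spatial scales; used
#' instead of ANOVA because within-scale betaNTI distributions are skewed.
#' Pairs are treated as independent observations, as is conventional in
#' distance-based community analyses, although pairs sharing a sample are
#' not strictly independent.
#'
#' @inheritParams scale_table
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis_scales <- function(B, bins) {
  stopifnot(inherits(B, "beta_nti"), inherits(bins, "pair_bins"))
  v <- B$beta_nti[cbind(bins$pairs$i, bins$pairs$j)]
  ok <- is.finite(v)
  g <- factor(bins$pairs$bin[ok])
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 non-empty bins")
  kt <- stats::kruskal.test(v[ok], droplevels(g))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}
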