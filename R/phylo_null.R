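#' Patristic distance matrix
#'
#' Pairwise sums of branch lengths along the tree path between every pair of
#' tips, in the tree's branch-length units.
#'
#' @param tree validated phylogeny.
#' @return symmetric matrix with zero diagonal, tips in `tree$tip.label`
#'   order.
#' @export
patristic_matrix <- function(tree) {
  tree <- validate_phylogeny(tree)
  D <- stats::cophenetic(tree)
  D[tree$tip.label, tree$tip.label]
}

# Weight matrix for the turnover statistics: relative abundance (weighted)
# or 1/richness over present taxa (presence-absence). Columns follow the
# taxa order of D.
turnover_weights <- function(table, D, weighted) {
  table <- validate_otu_table(table)
  if (!setequal(colnames(table), rownames(D)))
    stop("OTU table columns and distance-matrix taxa differ; harmonize first")
  X <- table[, rownames(D), drop = FALSE]
  W <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  pres <- X > 0
  if (weighted) {
    W[pres] <- X[pres]
    W <- W / rowSums(W)
  } else {
    W[pres] <- 1
    W <- W / rowSums(W)
  }
  W
}

#' Mean nearest taxon distance of one community
#'
#' For each taxon present in the community, the distance to its phylogenetic
#' nearest neighbour among the other present taxa, averaged with equal
#' weights (`weighted = FALSE`) or with relative abundances
#' (`weighted = TRUE`).
#'
#' @param counts named count (or abundance) vector over the taxa of `D`.
#' @param D patristic matrix.
#' @param weighted abundance-weight the mean? Default `TRUE`.
#' @return scalar MNTD.
#' @export
mntd <- function(counts, D, weighted = TRUE) {
  if (is.null(names(counts))) stop("counts must be named by taxon")
  counts <- counts[names(counts) %in% rownames(D)]
  present <- names(counts)[counts > 0]
  if (length(present) < 2L)
    stop("MNTD undefined for fewer than 2 present taxa")
  sub <- D[present, present, drop = FALSE]
  diag(sub) <- Inf
  nn <- apply(sub, 1, min)
  w <- if (weighted) counts[present] / sum(counts[present])
       else rep(1 / length(present), length(present))
  sum(w * nn)
}

#' Between-community mean nearest taxon distance
#'
#' `0.5 * [sum_i w_ai min_j D(i,j) + sum_j w_bj min_i D(i,j)]` where `i`
#' runs over taxa present in `a` and `j` over taxa present in `b`; a taxon
#' shared by both communities contributes distance zero.
#'
#' @param counts_a,counts_b named count vectors.
#' @param D patristic matrix.
#' @param weighted abundance weights (default) or equal weights over present
#'   taxa.
#' @return scalar betaMNTD.
#' @export
beta_mntd <- function(counts_a, counts_b, D, weighted = TRUE) {
  pa <- names(counts_a)[counts_a > 0]
  pb <- names(counts_b)[counts_b > 0]
  if (!length(pa) || !length(pb)) stop("empty community")
  sub <- D[pa, pb, drop = FALSE]
  wa <- if (weighted) counts_a[pa] / sum(counts_a[pa]) else rep(1 / length(pa), length(pa))
  wb <- if (weighted) counts_b[pb] / sum(counts_b[pb]) else rep(1 / length(pb), length(pb))
  0.5 * (sum(wa * apply(sub, 1, min)) + sum(wb * apply(sub, 2, min)))
}

# One matrix of taxa-label permutations (n_null x K, 0-based for C++),
# drawn from a single seeded stream.
null_permutations <- function(n_null, K, seed) {
  set.seed(as.integer(seed))
  P <- matrix(0L, n_null, K)
  for (r in seq_len(n_null)) P[r, ] <- sample.int(K) - 1L
  P
}

#' Null-standardized MNTD (ses.MNTD / NTI)
#'
#' Standardizes each sample's observed MNTD against a taxa-shuffle null:
#' tip labels of the patristic matrix are permuted `n_null` times (abundances
#' stay in their community slots) and MNTD is recomputed per shuffle.
#' `ses = (obs - mean_null) / sd_null`; the permutation quantile is
#' `p = (#\{null <= obs\} + 1) / (n_null + 1)`. Following the convention of
#' the soil-community literature this package reports ses.MNTD itself as the
#' Nearest Taxon Index (no sign flip; much of the older literature defines
#' NTI as `-ses.MNTD`).
#'
#' @param table OTU table, harmonized with `D`.
#' @param D patristic matrix.
#' @param n_null number of randomizations, default 999.
#' @param seed integer seed for the shared permutation stream.
#' @param weighted abundance-weighted MNTD (default `TRUE`).
#' @return data.frame with one row per sample: `sample_id`, `richness`,
#'   `mntd_obs`, `null_mean`, `null_sd`, `ses`, `p`; attributes `n_null` and
#'   `seed`. Samples with degenerate nulls (`sd = 0`) get `NA` ses with a
#'   warning.
#' @export
ses_mntd <- function(table, D, n_null = 999L, seed = 1L, weighted = TRUE) {
  if (n_null < 99L) stop("n_null must be >= 99")
  W <- turnover_weights(table, D, weighted)
  rich <- rowSums(W > 0)
  if (any(rich < 2L))
    stop("samples with fewer than 2 taxa: ",
         paste(rownames(W)[rich < 2], collapse = ", "))
  P <- null_permutations(n_null, ncol(W), seed)
  res <- .cpp_mntd_null(D, W, P)
  # a permutation-invariant community gives a numerically zero null sd
  sd0 <- !is.finite(res$sd) | res$sd <= 1e-10 * pmax(abs(res$mean), 1e-12)
  if (any(sd0))
    warning("null sd = 0 for ", sum(sd0), " sample(s); ses reported as NA")
  ses <- ifelse(sd0, NA_real_, (res$obs - res$mean) / res$sd)
  out <- data.frame(sample_id = rownames(W),
                    richness = as.integer(rich),
                    mntd_obs = as.numeric(res$obs),
                    null_mean = as.numeric(res$mean),
                    null_sd = as.numeric(res$sd),
                    ses = as.numeric(ses),
                    p = (as.numeric(res$count_le) + 1) / (n_null + 1),
                    stringsAsFactors = FALSE)
  attr(out, "n_null") <- as.integer(n_null)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "weighted") <- weighted
  out
}

#' Pairwise betaMNTD and betaNTI
#'
#' Computes observed betaMNTD for all sample pairs and standardizes it
#' against a taxa-shuffle null. One tip-label permutation per replicate is
#' applied to the patristic matrix and betaMNTD recomputed for *all* pairs
#' under that replicate (nulls are shared across pairs, which is what makes
#' hundreds of samples tractable; the per-pair independent-shuffle
#' brute-force oracle lives in the test suite).
#'
#' @inheritParams ses_mntd
#' @return object of class `beta_nti`: list with `sample_ids`,
#'   `beta_mntd` (observed, symmetric), `beta_nti` (symmetric, `NA`
#'   diagonal), `null_mean`, `null_sd`, `n_null`, `seed`, `weighted`.
#' @export
beta_nti <- function(table, D, n_null = 999L, seed = 1L, weighted = TRUE) {
  if (n_null < 99L) stop("n_null must be >= 99")
  W <- turnover_weights(table, D, weighted)
  if (nrow(W) < 2L) stop("need at least 2 samples")
  if (any(rowSums(W > 0) < 1L)) stop("empty sample")
  obs <- .cpp_beta_mntd(D, W)
  P <- null_permutations(n_null, ncol(W), seed)
  nul <- .cpp_beta_mntd_null(D, W, P)
  bnti <- (obs - nul$mean) / nul$sd
  sd0 <- !is.finite(nul$sd) | nul$sd <= 1e-10 * pmax(abs(nul$mean), 1e-12)
  diag(sd0) <- FALSE
  if (any(sd0))
    warning("null sd = 0 for ", sum(sd0) / 2, " pair(s); betaNTI set to NA")
  bnti[sd0] <- NA_real_
  diag(bnti) <- NA_real_
  dimnames(obs) <- dimnames(bnti) <- list(rownames(W), rownames(W))
  structure(list(sample_ids = rownames(W), beta_mntd = obs, beta_nti = bnti,
                 null_mean = nul$mean, null_sd = nul$sd,
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 weighted = weighted),
            class = "beta_nti")
}

#' @export
print.beta_nti <- function(x, ...) {
  cat("betaNTI over", length(x$sample_ids), "samples (",
      x$n_null, "randomizations,",
      if (x$weighted) "abundance-weighted" else "presence-absence", ")\n")
  v <- x$beta_nti[upper.tri(x$beta_nti)]
  cat("  median betaNTI:", round(median(v, na.rm = TRUE), 3),
      " |betaNTI|>2:", round(100 * mean(abs(v) > 2, na.rm = TRUE), 1), "%\n")
  invisible(x)
}

#' Classify sample pairs as deterministic or stochastic
#'
#' `|betaNTI| > threshold` marks a pair as deterministically assembled
#' (`homogeneous` selection when `betaNTI < -threshold`, `variable`
#' selection when `> threshold`); values inside the band, including exactly
#' at the boundary, are classed stochastic. Pairs with missing betaNTI are
#' excluded and counted.
#'
#' @param B `beta_nti` object or a symmetric betaNTI matrix.
#' @param threshold positive classification threshold, default 2.
#' @return data.frame of pairs (`sample_a`, `sample_b`, `beta_nti`, `label`,
#'   `sublabel`) with attribute `n_excluded`.
#' @export
classify_pairs <- function(B, threshold = 2) {
  if (threshold <= 0) stop("threshold must be > 0")
  M <- if (inherits(B, "beta_nti")) B$beta_nti else as.matrix(B)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  v <- M[idx]
  ok <- is.finite(v)
  lab <- ifelse(abs(v[ok]) > threshold, "deterministic", "stochastic")
  sub <- ifelse(v[ok] < -threshold, "homogeneous",
                ifelse(v[ok] > threshold, "variable", "none"))
  out <- data.frame(sample_a = rownames(M)[idx[ok, 1]],
                    sample_b = colnames(M)[idx[ok, 2]],
                    beta_nti = v[ok], label = lab, sublabel = sub,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Long-format export of a betaNTI result
#'
#' @param B `beta_nti` object.
#' @param threshold classification threshold passed to [classify_pairs()].
#' @return data.frame with one row per unordered pair: ids, betaMNTD,
#'   betaNTI and the process label.
#' @export
beta_nti_pairs <- function(B, threshold = 2) {
  stopifnot(inherits(B, "beta_nti"))
  cls <- classify_pairs(B, threshold)
  bm <- B$beta_mntd[cbind(match(cls$sample_a, B$sample_ids),
                          match(cls$sample_b, B$sample_ids))]
  cbind(cls[, c("sample_a", "sample_b")], beta_mntd = bm,
        cls[, c("beta_nti", "label", "sublabel")])
}
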