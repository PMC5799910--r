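#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a,b) = sum |x_ai - x_bi| / sum (x_ai + x_bi)`, computed with
#' [vegan::vegdist()].
#'
#' @param table OTU table (counts or relative abundances; every row total
#'   must be positive).
#' @return symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis_matrix <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) <= 0)) stop("samples with zero total abundance")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Per-sample alpha diversity
#'
#' Observed richness, Chao1, Shannon entropy (nats), Simpson evenness
#' (inverse Simpson / richness) plus plain inverse Simpson, and Faith
#' phylogenetic diversity (total branch length of the subtree spanning the
#' present tips, including the path to the root, via [picante::pd()]).
#' Chao1 uses the classic estimator `S + F1^2 / (2 F2)` and falls back to
#' the bias-corrected `S + F1 (F1 - 1) / (2 (F2 + 1))` when there are no
#' doubletons; with no singletons Chao1 equals the observed richness.
#'
#' @param table OTU table.
#' @param tree optional phylogeny covering the table's OTUs (needed for
#'   Faith PD).
#' @return data.frame with one row per sample: `sample_id`, `richness`,
#'   `chao1`, `shannon`, `simpson_evenness`, `inv_simpson`, and `faith_pd`
#'   when a tree is supplied.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  table <- validate_otu_table(table)
  S <- rowSums(table > 0)
  if (any(S < 1L)) stop("empty sample")
  F1 <- rowSums(table == 1L)
  F2 <- rowSums(table == 2L)
  chao1 <- ifelse(F1 == 0, S,
                  ifelse(F2 > 0, S + F1^2 / (2 * F2),
                         S + F1 * (F1 - 1) / (2 * (F2 + 1))))
  shannon <- vegan::diversity(table, index = "shannon")
  inv_simp <- vegan::diversity(table, index = "invsimpson")
  out <- data.frame(sample_id = rownames(table),
                    richness = as.integer(S), chao1 = as.numeric(chao1),
                    shannon = as.numeric(shannon),
                    simpson_evenness = as.numeric(inv_simp / S),
                    inv_simpson = as.numeric(inv_simp),
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    tree <- validate_phylogeny(tree)
    pd <- picante::pd(table[, tree$tip.label, drop = FALSE], tree,
                      include.root = TRUE)
    out$faith_pd <- pd$PD
  }
  rownames(out) <- out$sample_id
  out
}

#' Standardized Euclidean environmental distance
#'
#' Each requested variable is z-standardized (zero mean, unit variance over
#' the included samples) before computing Euclidean distances, so variables
#' with incommensurate units contribute equally. Constant variables are
#' dropped with a warning; samples with missing values in the requested
#' variables are dropped with a message.
#'
#' @param meta sample metadata.
#' @param variables environmental columns to use; default all numeric
#'   environmental columns ([env_variables()]).
#' @return symmetric distance matrix over the retained samples.
#' @export
env_distance <- function(meta, variables = env_variables(meta)) {
  meta <- validate_sample_metadata(meta)
  if (!length(variables)) stop("no environmental variables")
  X <- as.matrix(meta[, variables, drop = FALSE])
  keep <- complete.cases(X)
  if (any(!keep)) {
    log_msg("dropping ", sum(!keep), " sample(s) with missing environment")
    X <- X[keep, , drop = FALSE]
  }
  if (nrow(X) < 2L) stop("fewer than 2 samples with complete environment")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    if (!ncol(X)) stop("all variables constant")
  }
  D <- as.matrix(dist(scale(X)))
  dimnames(D) <- list(meta$sample_id[keep], meta$sample_id[keep])
  D
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorized upper triangles, with significance
#' from simultaneous row/column permutations of one matrix
#' (via [vegan::mantel()]; `p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1)`).
#'
#' @param Dx,Dy square distance matrices over the same samples (same order).
#' @param n_perm number of permutations, default 999.
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(Dx, Dy, n_perm = 999L, seed = 1L) {
  Dx <- as.matrix(Dx); Dy <- as.matrix(Dy)
  if (!all(dim(Dx) == dim(Dy))) stop("matrices differ in size")
  if (nrow(Dx) < 4L) stop("need at least 4 samples for a Mantel test")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  set.seed(as.integer(seed))
  mt <- vegan::mantel(stats::as.dist(Dx), stats::as.dist(Dy),
                      method = "pearson", permutations = n_perm)
  list(r = unname(mt$statistic), p = unname(mt$signif),
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Distance decay of community similarity
#'
#' Ordinary least squares of log similarity on geographic distance over
#' pairs with positive similarity (the standard log-linear decay form;
#' `log_distance = TRUE` gives the power-law variant regressing on log
#' distance instead).
#'
#' @param sim similarity matrix, e.g. `1 - bray_curtis_matrix(x)`.
#' @param G geographic distance matrix (km), same samples and order.
#' @param log_distance regress on `log(distance)` instead of distance.
#' @return list with `slope` (per km), `intercept`, `r2`, `n_pairs`,
#'   `n_excluded` (zero-similarity pairs).
#' @export
distance_decay <- function(sim, G, log_distance = FALSE) {
  sim <- as.matrix(sim); G <- as.matrix(G)
  if (!all(dim(sim) == dim(G))) stop("matrices differ in size")
  s <- sim[upper.tri(sim)]
  d <- G[upper.tri(G)]
  keep <- s > 0
  if (!any(keep)) stop("all similarities are zero")
  x <- if (log_distance) log(d[keep]) else d[keep]
  y <- log(s[keep])
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2, n_pairs = sum(keep), n_excluded = sum(!keep))
}

#' Pearson correlations between alpha diversity and environment
#'
#' One two-sided Pearson test per (diversity index, environmental variable)
#' pair, with pairwise deletion of missing values. Constant columns yield
#' `NA` with a warning.
#'
#' @param alpha output of [alpha_diversity()].
#' @param meta sample metadata (matched by `sample_id`).
#' @param variables environmental columns; default [env_variables()].
#' @return data.frame with `index`, `variable`, `r`, `p`, `n`.
#' @export
alpha_env_correlation <- function(alpha, meta,
                                  variables = env_variables(meta)) {
  meta <- validate_sample_metadata(meta)
  common <- intersect(alpha$sample_id, meta$sample_id)
  if (length(common) < 3L) stop("fewer than 3 paired observations")
  alpha <- alpha[match(common, alpha$sample_id), ]
  meta <- meta[common, ]
  idx <- setdiff(names(alpha), "sample_id")
  out <- list()
  for (iv in idx) for (ev in variables) {
    a <- alpha[[iv]]; e <- meta[[ev]]
    ok <- is.finite(a) & is.finite(e)
    if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(e[ok]) == 0) {
      warning("constant or insufficient data for ", iv, " vs ", ev)
      out[[length(out) + 1L]] <- data.frame(index = iv, variable = ev,
                                            r = NA_real_, p = NA_real_,
                                            n = sum(ok))
      next
    }
    ct <- cor.test(a[ok], e[ok], method = "pearson")
    out[[length(out) + 1L]] <- data.frame(index = iv, variable = ev,
                                          r = unname(ct$estimate),
                                          p = ct$p.value, n = sum(ok))
  }
  do.call(rbind, out)
}
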