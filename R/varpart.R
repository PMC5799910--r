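#' Transform a community matrix for linear ordination
#'
#' `hellinger` (default, the square root of relative abundances, whose rows
#' have unit Euclidean norm), `proportion`, or `none`.
#'
#' @param table OTU table (counts or proportions; positive row totals).
#' @param method transformation name.
#' @return numeric matrix with attribute `transformation`.
#' @export
transform_response <- function(table,
                               method = c("hellinger", "proportion", "none")) {
  method <- match.arg(method)
  Y <- as.matrix(table)
  if (any(rowSums(Y) <= 0)) stop("samples with zero total abundance")
  Y <- switch(method,
              hellinger = sqrt(sweep(Y, 1, rowSums(Y), "/")),
              proportion = sweep(Y, 1, rowSums(Y), "/"),
              none = Y)
  attr(Y, "transformation") <- method
  Y
}

# Drop collinear predictor columns by pivoted QR rank detection.
prune_collinear <- function(X, tol = 1e-8) {
  qrx <- qr(X, tol = tol)
  if (qrx$rank < ncol(X)) {
    drop <- qrx$pivot[seq(qrx$rank + 1L, ncol(X))]
    warning("dropping ", length(drop), " collinear predictor column(s)")
    X <- X[, -drop, drop = FALSE]
  }
  X
}

#' Redundancy-analysis R-squared of a predictor block
#'
#' Multivariate least squares of the centred response on the centred
#' predictors; `R2` is the share of the response's total sum of squares
#' captured by the fitted values, and the adjusted value uses the Ezekiel
#' correction `1 - (1 - R2) (n - 1) / (n - p - 1)` with `p` the (detected)
#' rank of the predictor block.
#'
#' @param Y response matrix (samples x variables), e.g. from
#'   [transform_response()].
#' @param X predictor matrix (samples x predictors).
#' @return list with `r2`, `adj_r2`, `rank`.
#' @export
rda_adjusted_r2 <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X row counts differ")
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Xc <- prune_collinear(Xc)
  p <- ncol(Xc)
  if (n <= p + 1L) stop("need more samples than predictors + 1")
  fit <- qr.fitted(qr(Xc), Yc)
  r2 <- sum(fit^2) / sum(Yc^2)
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1), rank = p)
}

block_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "pcnm_basis")) return(x$vectors)
  as.matrix(x)
}

#' Variance partitioning among environment, trend and spatial blocks
#'
#' Partitions the adjusted variance of a community response among up to
#' three predictor blocks (typically: standardized environmental variables,
#' a latitudinal trend, and PCNM spatial axes) by inclusion-exclusion over
#' the adjusted R-squared of the seven block unions. Closed-form symmetric
#' formulas are used for every fraction, so the partition is exactly
#' invariant to block order and the seven fractions plus the residual sum
#' to one by construction. Adjusted fractions can be individually negative.
#'
#' @param Y response matrix (samples x OTUs), e.g. Hellinger-transformed.
#' @param env,trend,spatial predictor blocks (matrix, data.frame, vector or
#'   [pcnm_axes()] result); at least one non-`NULL`.
#' @return object of class `varpart_fractions`: list with `pure_env`,
#'   `pure_trend`, `pure_spatial`, `shared_env_trend`, `shared_env_spatial`,
#'   `shared_trend_spatial`, `shared_all`, `residual`, `r2_total`
#'   (unadjusted R2 of all blocks), `adj_total`, and `blocks` (which blocks
#'   were supplied).
#' @export
partition_three <- function(Y, env = NULL, trend = NULL, spatial = NULL) {
  Y <- as.matrix(Y)
  blocks <- list(env = block_matrix(env), trend = block_matrix(trend),
                 spatial = block_matrix(spatial))
  have <- !vapply(blocks, is.null, logical(1))
  if (!any(have)) stop("supply at least one predictor block")
  adj <- function(parts) {
    X <- do.call(cbind, blocks[parts])
    # canonical column order: the union's fit depends only on the set of
    # predictors, making the partition bitwise invariant to block order
    X <- X[, do.call(order, as.data.frame(t(X))), drop = FALSE]
    rda_adjusted_r2(Y, X)$adj_r2
  }
  # adjusted R2 of every non-empty union of the supplied blocks; absent
  # blocks behave as explaining exactly nothing.
  nm <- names(blocks)
  A <- list()
  for (k in 1:3) for (parts in utils::combn(nm, k, simplify = FALSE)) {
    key <- paste(parts, collapse = "+")
    used <- parts[have[parts]]
    A[[key]] <- if (length(used)) adj(used) else 0
  }
  u <- function(...) {
    parts <- nm[nm %in% c(...)]  # canonical block order
    A[[paste(parts, collapse = "+")]]
  }
  all3 <- u("env", "trend", "spatial")
  pure <- function(x) {
    others <- setdiff(nm, x)
    all3 - u(others)
  }
  shared2 <- function(x, y) {
    z <- setdiff(nm, c(x, y))
    u(x, z) + u(y, z) - u(z) - all3
  }
  res <- list(
    pure_env = pure("env"),
    pure_trend = pure("trend"),
    pure_spatial = pure("spatial"),
    shared_env_trend = shared2("env", "trend"),
    shared_env_spatial = shared2("env", "spatial"),
    shared_trend_spatial = shared2("trend", "spatial"),
    shared_all = u("env") + u("trend") + u("spatial") -
      u("env", "trend") - u("env", "spatial") - u("trend", "spatial") + all3,
    residual = 1 - all3,
    adj_total = all3,
    r2_total = rda_adjusted_r2(Y, do.call(cbind, blocks[have]))$r2,
    blocks = nm[have])
  class(res) <- "varpart_fractions"
  res
}

#' @export
print.varpart_fractions <- function(x, ...) {
  cat("Variance partition (adjusted R2 fractions):\n")
  f <- unlist(x[c("pure_env", "pure_trend", "pure_spatial",
                  "shared_env_trend", "shared_env_spatial",
                  "shared_trend_spatial", "shared_all", "residual")])
  for (n in names(f)) cat(sprintf("  %-22s %8.4f\n", n, f[[n]]))
  cat(sprintf("  total adjusted R2: %.4f (unadjusted %.4f)\n",
              x$adj_total, x$r2_total))
  invisible(x)
}

#' @export
as.data.frame.varpart_fractions <- function(x, ...) {
  f <- c("pure_env", "pure_trend", "pure_spatial", "shared_env_trend",
         "shared_env_spatial", "shared_trend_spatial", "shared_all",
         "residual")
  data.frame(fraction = f, adj_r2 = unlist(x[f]), row.names = NULL)
}
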