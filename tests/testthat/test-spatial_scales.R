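test_that("haversine distances use Earth radius 6371 km", {
  meta <- data.frame(sample_id = c("p", "q", "r"), site_id = "x",
                     longitude = c(0, 90, 0), latitude = c(0, 0, 0))
  G <- geodesic_matrix(meta)
  expect_equal(G["p", "q"], 6371 * pi / 2, tolerance = 1e-6)
  expect_equal(G["p", "r"], 0)
  expect_equal(G, t(G))
  expect_equal(unname(diag(G)), rep(0, 3))
  meta$latitude[1] <- NA
  expect_error(geodesic_matrix(meta), "latitude|coordinates")
})

# independent PCNM oracle: truncate, double-centre -d^2/2, dense eigen
pcnm_oracle <- function(G, threshold) {
  d <- as.matrix(G)
  d[d > threshold] <- 4 * threshold
  A <- -0.5 * d^2
  n <- nrow(A)
  C <- diag(n) - matrix(1 / n, n, n)
  eigen(C %*% A %*% C, symmetric = TRUE)
}

test_that("PCNM axes match a dense eigensolver oracle on a line transect", {
  xy <- data.frame(sample_id = sprintf("p%02d", 1:12), site_id = "x",
                   longitude = 0, latitude = seq(0, 1, length.out = 12))
  G <- geodesic_matrix(xy)
  p <- pcnm_axes(G)
  # vegan's auto threshold for a line = the point spacing (longest MST edge)
  spacing <- G[1, 2]
  expect_equal(p$threshold, spacing, tolerance = 1e-8)
  eo <- pcnm_oracle(G, p$threshold)
  pos <- eo$values > 1e-8 * max(eo$values)
  expect_equal(p$values, eo$values[pos], tolerance = 1e-8)
  for (k in seq_along(p$values)) {
    v <- eo$vectors[, k]
    expect_equal(abs(sum(v * p$vectors[, k])), 1, tolerance = 1e-8)  # up to sign
  }
  # orthonormality
  crossdots <- crossprod(p$vectors) - diag(ncol(p$vectors))
  expect_lt(max(abs(crossdots)), 1e-8)
  # reconstruction of the centred truncated matrix's positive part
  Cpos <- eo$vectors[, pos] %*% diag(eo$values[pos]) %*% t(eo$vectors[, pos])
  Rec <- p$vectors %*% diag(p$values, length(p$values)) %*% t(p$vectors)
  expect_lt(sqrt(sum((Cpos - Rec)^2)), 1e-6)
})

test_that("three collinear equidistant points give one symmetric axis", {
  G <- as.matrix(dist(c(0, 1, 2)))
  dimnames(G) <- list(paste0("p", 1:3), paste0("p", 1:3))
  p <- pcnm_axes(G, truncation = 2)
  expect_equal(length(p$values), 1L)
  expect_equal(p$vectors[1, 1], -p$vectors[3, 1], tolerance = 1e-10)
  expect_equal(p$vectors[2, 1], 0, tolerance = 1e-10)
  expect_error(pcnm_axes(matrix(0, 3, 3)), "identical")
})

test_that("equal-width pair bins cover the observed range", {
  # pair-distance multiset spanning [1, 4]: two bins of width 1.5
  G <- matrix(0, 4, 4, dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  G[upper.tri(G)] <- c(1, 2, 3, 4, 1.5, 3.2)
  G <- G + t(G)
  b <- bin_pairs(G, n_bins = 2)
  expect_equal(b$centers, c(1.75, 3.25))
  expect_equal(b$pairs$bin[b$pairs$distance <= 2], rep(1L, 3))   # {1, 2, 1.5}
  expect_equal(b$pairs$bin[b$pairs$distance >= 2.5], rep(2L, 3)) # {3, 4, 3.2}
  expect_equal(nrow(b$pairs), 6L)
  expect_warning(bin_pairs(G, n_bins = 1), "single bin")
  # every pair in exactly one bin even with empty bins
  b16 <- suppressWarnings(bin_pairs(G, n_bins = 16))
  expect_equal(sum(table(b16$pairs$bin)), choose(4, 2))
})

test_that("the scale table counts deterministic and stochastic pairs exactly", {
  # craft a betaNTI object with known values in known bins
  ids <- paste0("s", 1:5)
  M <- matrix(NA_real_, 5, 5, dimnames = list(ids, ids))
  vals <- c(-2.5, -1, 0, 1, 5, 5, 5, 5, 0.5, 0.5)
  M[upper.tri(M)] <- vals
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  B <- structure(list(sample_ids = ids, beta_nti = M, beta_mntd = M,
                      n_null = 999L, seed = 1L, weighted = TRUE),
                 class = "beta_nti")
  G <- matrix(0, 5, 5, dimnames = list(ids, ids))
  # four near pairs (~10 km) and six far pairs (~1000 km): with four bins
  # the middle two stay empty and the end bins land in the small/large bands
  d <- c(10, 11, 12, 13, 995, 996, 997, 998, 999, 1000)
  G[upper.tri(G)] <- d; G <- G + t(G)
  bins <- bin_pairs(G, n_bins = 4)
  st <- scale_table(B, bins)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  vv <- M[ut]; dd <- G[ut]
  expect_equal(st$median_bnti[1], median(vv[dd < 500]))
  expect_equal(st$deterministic_pct[1], 100 * mean(abs(vv[dd < 500]) > 2))
  expect_equal(st$deterministic_pct[4], 100 * mean(abs(vv[dd > 500]) > 2))
  expect_equal(st$deterministic_pct[c(1, 4)] + st$stochastic_pct[c(1, 4)],
               c(100, 100))
  # empty bins are emitted with zero pairs and missing statistics
  expect_equal(st$n_pairs[2:3], c(0L, 0L))
  expect_true(all(is.na(st$median_bnti[2:3])))
  expect_equal(as.character(st$band[c(1, 4)]), c("small", "large"))
  expect_equal(sum(st$n_pairs), choose(5, 2))
})

test_that("bins with only in-band values report 0% determinism", {
  ids <- paste0("s", 1:4)
  M <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(M) <- NA
  B <- structure(list(sample_ids = ids, beta_nti = M, beta_mntd = M,
                      n_null = 999L, seed = 1L, weighted = TRUE),
                 class = "beta_nti")
  G <- as.matrix(dist(c(0, 10, 20, 30))); dimnames(G) <- list(ids, ids)
  st <- suppressWarnings(scale_table(B, bin_pairs(G, 2)))
  expect_equal(st$deterministic_pct, c(0, 0))
  expect_equal(st$stochastic_pct, c(100, 100))
})

test_that("Kruskal-Wallis across bins matches the closed-form toy", {
  ids <- paste0("s", 1:4)
  make_B <- function(vals) {
    M <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
    M[upper.tri(M)] <- vals
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    structure(list(sample_ids = ids, beta_nti = M, beta_mntd = M,
                   n_null = 999L, seed = 1L, weighted = TRUE),
              class = "beta_nti")
  }
  G <- matrix(0, 4, 4, dimnames = list(ids, ids))
  G[upper.tri(G)] <- c(1, 1, 1, 9, 9, 9); G <- G + t(G)
  bins <- bin_pairs(G, 2)
  ut <- which(upper.tri(G), arr.ind = TRUE)
  near_first <- G[ut] < 5
  vals <- numeric(6); vals[near_first] <- c(1, 2, 3); vals[!near_first] <- c(10, 11, 12)
  kw <- kruskal_wallis_scales(make_B(vals), bins)
  expect_equal(kw$H, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2),
               tolerance = 1e-6)  # 3.857 for complete separation at n=6
  expect_equal(kw$df, 1L)
  expect_lt(kw$p, 0.05)
  # rank statistic: invariant to strictly monotone transforms
  kw2 <- kruskal_wallis_scales(make_B(exp(vals)), bins)
  expect_equal(kw2$H, kw$H)
  # identical multisets across bins: no separation
  vals0 <- numeric(6); vals0[near_first] <- c(1, 2, 3); vals0[!near_first] <- c(1, 2, 3)
  kw0 <- kruskal_wallis_scales(make_B(vals0), bins)
  expect_equal(kw0$H, 0, tolerance = 1e-12)
  expect_gt(kw0$p, 0.9)
})
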