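test_that("patristic distances are path sums with metric structure", {
  D <- patristic_matrix(cherry_tree())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["C", "D"], 2)
  expect_equal(unname(D["A", c("C", "D")]), c(6, 6))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  Ds <- patristic_matrix(star_tree(5))
  expect_true(all(Ds[upper.tri(Ds)] == 2))
})

test_that("MNTD matches hand-enumerated nearest neighbours", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  x <- c(A = 1, B = 1, C = 1)
  expect_equal(mntd(x, D, weighted = FALSE), 8 / 3)
  expect_equal(mntd(x, D, weighted = TRUE), 8 / 3)  # uniform weights
  expect_equal(mntd(c(A = 3, B = 2, C = 0), D), 2)  # two taxa: their distance
  expect_error(mntd(c(A = 1, B = 0, C = 0), D), "fewer than 2")
})

test_that("betaMNTD matches hand computation on the cherry tree", {
  D <- patristic_matrix(cherry_tree())
  a <- c(A = 1, B = 1, C = 0, D = 0)
  b <- c(A = 0, B = 0, C = 1, D = 1)
  expect_equal(beta_mntd(a, b, D), 6)           # all cross-cherry minima are 6
  expect_equal(beta_mntd(a, a, D), 0)           # identical communities
  expect_equal(beta_mntd(c(A = 2, B = 0, C = 0, D = 0),
                         c(A = 0, B = 5, C = 0, D = 0), D), 2)
  expect_error(beta_mntd(a, c(A = 0, B = 0, C = 0, D = 0), D), "empty")
})

test_that("single-pair betaMNTD, the C++ all-pairs kernel and picante agree", {
  fx <- random_fixture(N = 8, K = 25, seed = 11)
  B <- beta_nti(fx$table, fx$D, n_null = 99, seed = 1)
  for (i in c(1, 3)) for (j in c(5, 8)) {
    expect_equal(B$beta_mntd[i, j],
                 beta_mntd(fx$table[i, ], fx$table[j, ], fx$D),
                 tolerance = 1e-12)
  }
  pic <- as.matrix(picante::comdistnt(as.data.frame(unclass(fx$table)),
                                      fx$D, abundance.weighted = TRUE))
  expect_equal(unname(B$beta_mntd[upper.tri(B$beta_mntd)]),
               unname(pic[upper.tri(pic)]), tolerance = 1e-10)
  pm <- picante::mntd(as.data.frame(unclass(fx$table)), fx$D,
                      abundance.weighted = TRUE)
  ours <- vapply(seq_len(8), function(i) mntd(fx$table[i, ], fx$D),
                 numeric(1))
  expect_equal(unname(ours), unname(pm), tolerance = 1e-10)
})

test_that("ses.MNTD agrees with picante's taxa-label null on a small fixture", {
  fx <- random_fixture(N = 8, K = 20, seed = 3)
  s <- ses_mntd(fx$table, fx$D, n_null = 999, seed = 2)
  pic <- picante::ses.mntd(as.data.frame(unclass(fx$table)), fx$D,
                           null.model = "taxa.labels", runs = 999,
                           abundance.weighted = TRUE)
  expect_equal(s$mntd_obs, pic$mntd.obs, tolerance = 1e-10)
  # independent permutation streams: z-scores agree within Monte Carlo noise
  expect_lt(max(abs(s$ses - pic$mntd.obs.z)), 0.35)
})

test_that("betaNTI is symmetric and floors at strongly negative for near-clones", {
  fx <- random_fixture(N = 6, K = 25, seed = 9)
  tab <- fx$table
  # exact clones are permutation-invariant (betaMNTD stays 0 under every
  # taxa shuffle): degenerate null, reported as NA with a warning
  tab[2, ] <- tab[1, ]
  expect_warning(Bc <- beta_nti(validate_otu_table(tab), fx$D,
                                n_null = 199, seed = 4), "null sd")
  expect_true(is.na(Bc$beta_nti[1, 2]))
  expect_equal(Bc$beta_mntd[1, 2], 0)
  # communities confined to one clade: turnover among close relatives sits
  # far below the taxa-shuffle null
  tree <- simulate_tree(40, seed = 31)
  D <- patristic_matrix(tree)
  clades <- ape::prop.part(tree)
  sizes <- lengths(clades)
  clade <- clades[[which(sizes >= 10 & sizes <= 14)[1]]]
  set.seed(8)
  tab2 <- matrix(0L, 6, 40, dimnames = list(paste0("s", 1:6), tree$tip.label))
  for (i in 1:6) tab2[i, sample(clade, 8)] <- 1L
  B <- beta_nti(validate_otu_table(tab2), D, n_null = 499, seed = 4)
  expect_identical(B$beta_nti, t(B$beta_nti))
  expect_lt(median(B$beta_nti[upper.tri(B$beta_nti)]), -2)
})

test_that("doubling branch lengths doubles distances but not z-scores", {
  fx <- random_fixture(N = 8, K = 25, seed = 21)
  B1 <- beta_nti(fx$table, fx$D, n_null = 199, seed = 6)
  B2 <- beta_nti(fx$table, 2 * fx$D, n_null = 199, seed = 6)
  expect_equal(B2$beta_mntd, 2 * B1$beta_mntd, tolerance = 1e-12)
  expect_equal(B2$beta_nti, B1$beta_nti, tolerance = 1e-10)
  s1 <- ses_mntd(fx$table, fx$D, n_null = 199, seed = 6)
  s2 <- ses_mntd(fx$table, 2 * fx$D, n_null = 199, seed = 6)
  expect_equal(s2$mntd_obs, 2 * s1$mntd_obs, tolerance = 1e-12)
  expect_equal(s2$ses, s1$ses, tolerance = 1e-10)
})

test_that("degenerate communities yield missing z-scores with a warning", {
  fx <- random_fixture(N = 3, K = 10, seed = 2)
  tab <- fx$table
  tab[, ] <- 1L  # every taxon everywhere: shuffles change nothing
  expect_warning(s <- ses_mntd(validate_otu_table(tab), fx$D,
                               n_null = 99, seed = 1), "null sd")
  expect_true(all(is.na(s$ses)))
  expect_error(ses_mntd(fx$table, fx$D, n_null = 9, seed = 1), ">= 99")
})

test_that("pair classification follows the strict two-sided threshold", {
  M <- matrix(NA_real_, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  M[upper.tri(M)] <- c(-1.41, -2.83, 2.0, 2.4, -2.0, NA)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  cls <- classify_pairs(M)
  lab <- setNames(cls$label, paste(cls$sample_a, cls$sample_b))
  expect_equal(unname(lab["a b"]), "stochastic")     # -1.41
  expect_equal(unname(lab["a c"]), "deterministic")  # -2.83
  expect_equal(unname(lab["b c"]), "stochastic")     # exactly 2: boundary
  expect_equal(unname(lab["a d"]), "deterministic")  # 2.4, variable
  expect_equal(cls$sublabel[cls$beta_nti == 2.4], "variable")
  expect_equal(cls$sublabel[cls$beta_nti == -2.83], "homogeneous")
  expect_equal(unname(lab["b d"]), "stochastic")     # exactly -2: boundary
  expect_equal(attr(cls, "n_excluded"), 1L)
  expect_error(classify_pairs(M, threshold = 0), "> 0")
})
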