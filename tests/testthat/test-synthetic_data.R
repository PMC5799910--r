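test_that("simulated trees are ultrametric with unit depth", {
  tr2 <- simulate_tree(2, seed = 1)
  d <- ape::node.depth.edgelength(tr2)
  expect_equal(unname(d[1:2]), c(1, 1), tolerance = 1e-9)
  tr <- simulate_tree(40, seed = 2)
  depths <- ape::node.depth.edgelength(tr)[seq_len(40)]
  expect_lt(max(abs(depths - 1)), 1e-9)
  expect_equal(tr$Nnode, 39L)                 # binary: n - 1 internal nodes
  expect_equal(length(tr$tip.label), 40L)
  # reproducibility
  expect_identical(ape::write.tree(simulate_tree(15, seed = 9)),
                   ape::write.tree(simulate_tree(15, seed = 9)))
})

test_that("Brownian traits have the BM variance and covariance structure", {
  # fixed cherry: tips split at depth 0.5 -> shared path 0.5
  tree <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  draws <- vapply(1:500, function(s) simulate_traits(tree, sigma2 = 1,
                                                     seed = s)[c("A", "B")],
                  numeric(2))
  expect_lt(abs(cov(draws[1, ], draws[2, ]) - 0.5), 0.15 * 0.5 + 0.05)
  expect_lt(abs(var(draws[1, ]) - 1), 0.15)
  # rate scaling near zero collapses all optima to the root value
  tiny <- simulate_traits(simulate_tree(30, seed = 4), sigma2 = 1e-12,
                          seed = 1)
  expect_lt(max(abs(tiny)), 1e-4)
})

test_that("rate decay concentrates trait change onto deep branches", {
  tree <- simulate_tree(100, seed = 6)
  plain <- vapply(1:60, function(s)
    simulate_traits(tree, seed = s), numeric(100))
  frozen <- vapply(1:60, function(s)
    simulate_traits(tree, seed = s, rate_decay = 12), numeric(100))
  # sister-tip differences shrink sharply relative to overall spread
  D <- patristic_matrix(tree); diag(D) <- Inf
  sisters <- cbind(seq_len(100), apply(D, 1, which.min))
  rel_diff <- function(M) {
    mean(vapply(seq_len(ncol(M)), function(k)
      mean(abs(M[sisters[, 1], k] - M[sisters[, 2], k])) / sd(M[, k]),
      numeric(1)))
  }
  expect_lt(rel_diff(frozen), 0.3 * rel_diff(plain))
})

test_that("the landscape carries the step and maps onto a meridian", {
  land <- simulate_landscape(n_sites = 10, plots_per_site = 3,
                             extent_km = 500, step_position_km = 250,
                             step_height = 2, noise_sd = 0.01, seed = 3)
  m <- land$meta
  expect_equal(nrow(m), 30L)
  south <- m$env[m$position_km < 250]; north <- m$env[m$position_km > 250]
  expect_lt(abs(mean(south) - 0), 0.1)
  expect_lt(abs(mean(north) - 2), 0.1)
  # geodesic distances reproduce transect distances
  G <- geodesic_matrix(m)
  expect_equal(G[1, 30], abs(m$position_km[1] - m$position_km[30]),
               tolerance = 1e-3)
  # no step: stationary environment
  flat <- simulate_landscape(n_sites = 20, plots_per_site = 5,
                             step_height = 0, noise_sd = 0.3, seed = 4)$meta
  half <- flat$position_km > 550
  se <- 0.3 * sqrt(1 / sum(half) + 1 / sum(!half))
  expect_lt(abs(mean(flat$env[half]) - mean(flat$env[!half])), 3 * se)
})

test_that("local communities have fixed size and honour the niche filter", {
  tree <- simulate_tree(40, seed = 5)
  meta <- simulate_landscape(n_sites = 4, plots_per_site = 2,
                             step_height = 0, noise_sd = 0, seed = 2)$meta
  # hand-built perfectly conserved niche: clade {first 5 tips} at 0, rest at 5
  traits <- setNames(c(rep(0, 5), rep(5, 35)), tree$tip.label)
  asm <- assemble_communities(tree, traits, meta, sigma_f = 0.1, m = 1,
                              theta = 100, J = 500, seed = 3)
  expect_true(all(rowSums(asm$table) == 500))
  clade_share <- rowSums(asm$table[, 1:5]) / 500
  expect_true(all(clade_share >= 0.9))  # exp-dominated weights
  expect_error(assemble_communities(tree, traits, meta, sigma_f = -1), "> 0")
})

test_that("neutral assembly with full immigration is multinomial sampling", {
  tree <- simulate_tree(40, seed = 8)
  meta <- simulate_landscape(n_sites = 1, plots_per_site = 1,
                             step_height = 0, noise_sd = 0, seed = 1)$meta
  traits <- simulate_traits(tree, seed = 2)
  asm <- assemble_communities(tree, traits, meta, sigma_f = Inf, m = 1,
                              theta = 50, J = 10000, seed = 4)
  x <- as.numeric(asm$table[1, ])
  p <- asm$meta_relabund
  # pool cells with small expectation, then chi-square goodness of fit
  grp <- ifelse(10000 * p >= 5, seq_along(p), 0L)
  obs <- tapply(x, grp, sum)
  pr <- tapply(p, grp, sum)
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("datasets are reproducible byte for byte under a fixed seed", {
  s1 <- simulate_dataset("neutral", n_taxa = 30, n_sites = 4,
                         plots_per_site = 2, J = 200, seed = 77)
  s2 <- simulate_dataset("neutral", n_taxa = 30, n_sites = 4,
                         plots_per_site = 2, J = 200, seed = 77)
  expect_identical(unclass(s1$table), unclass(s2$table))
  expect_identical(s1$meta, s2$meta)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  s3 <- simulate_dataset("neutral", n_taxa = 30, n_sites = 4,
                         plots_per_site = 2, J = 200, seed = 78)
  expect_false(identical(unclass(s1$table), unclass(s3$table)))
})

test_that("truth records document the generating regime", {
  sim <- simulate_dataset("homogeneous_selection", n_taxa = 60, n_sites = 4,
                          plots_per_site = 2, seed = 5)
  expect_equal(sim$truth$process, "homogeneous_selection")
  expect_equal(sim$truth$m, 1)
  expect_gt(sim$truth$sigma_f, 0)
  expect_true(all(rowSums(sim$table) == sim$truth$J))
  d <- tempfile()
  paths <- write_synthetic_dataset(sim, d)
  expect_true(all(file.exists(paths)))
  rt <- read_otu_table(paths["table"])
  expect_equal(unclass(rt)[, ], unclass(sim$table)[, ])
  tru <- jsonlite::read_json(paths["truth"])
  expect_equal(tru$process, "homogeneous_selection")
})
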