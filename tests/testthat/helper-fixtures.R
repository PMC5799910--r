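# Shared fixtures, all built in code.

cherry_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2):0;")
}

star_tree <- function(n = 4) {
  ape::read.tree(text = paste0("(", paste0(LETTERS[1:n], ":1", collapse = ","),
                               ");"))
}

# counts matrix with named dims
cmat <- function(x, samples, otus) {
  matrix(as.integer(x), length(samples), length(otus), byrow = TRUE,
         dimnames = list(samples, otus))
}

# random harmonized fixture: N samples over the tips of a simulated tree
random_fixture <- function(N = 10, K = 30, seed = 42, lambda = 2) {
  tree <- simulate_tree(K, seed = seed)
  set.seed(seed + 1)
  tab <- matrix(rpois(N * K, lambda), N, K,
                dimnames = list(sprintf("s%02d", seq_len(N)), tree$tip.label))
  # guarantee >= 2 taxa everywhere
  for (i in seq_len(N)) if (sum(tab[i, ] > 0) < 2) tab[i, 1:2] <- 1L
  list(table = validate_otu_table(tab), tree = tree,
       D = patristic_matrix(tree))
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
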