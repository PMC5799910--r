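#' OTU count tables
#'
#' An OTU table is stored as a base integer matrix with samples in rows and
#' OTUs in columns; `rownames` are sample identifiers, `colnames` are OTU
#' identifiers. `otu_table()` validates a matrix and stamps the class
#' `"otu_table"` (the class is a marker only -- every function in the package
#' also accepts a plain validated matrix).
#'
#' @param counts numeric matrix of non-negative whole numbers, samples x OTUs,
#'   with unique non-empty row and column names.
#' @return the validated integer matrix with class `otu_table`.
#' @examples
#' otu_table(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("o1", "o2", "o3"))))
#' @export
otu_table <- function(counts) {
  counts <- validate_otu_table(counts)
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' Validate an OTU table
#'
#' Checks the invariants required throughout the package: a samples x OTUs
#' matrix of non-negative integers with unique identifiers, at least one
#' sample and at least two OTUs.
#'
#' @param counts matrix to validate.
#' @return the matrix with integer storage (invisibly usable as-is).
#' @export
validate_otu_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table must have sample (row) and OTU (column) names")
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s))
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  dup_o <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_o))
    stop("duplicated OTU ids: ", paste(dup_o, collapse = ", "))
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("OTU table needs at least 1 sample and 2 OTUs")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at [",
         rownames(counts)[bad[1, 1]], ", ", colnames(counts)[bad[1, 2]],
         "]: ", counts[bad[1, , drop = FALSE]])
  storage.mode(counts) <- "integer"
  counts
}

#' Read an OTU count table from TSV
#'
#' The file is tab-separated with the first column holding identifiers of one
#' axis and the header the other. Orientation is auto-detected from the
#' header's corner token (`sample`/`sample_id` means rows are samples;
#' `otu`/`otu_id`/`#OTU ID`/`taxon`/`species` means rows are OTUs) and can be
#' forced with `orientation`. The returned table is always samples x OTUs.
#'
#' @param path path to a TSV file.
#' @param orientation `"auto"` (default), `"samples_rows"` or `"otus_rows"`.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path,
                           orientation = c("auto", "samples_rows", "otus_rows")) {
  orientation <- match.arg(orientation)
  raw <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
  header <- readLines(path, n = 50L)
  header <- header[!startsWith(header, "#")][1]
  corner <- tolower(strsplit(header, "\t", fixed = TRUE)[[1]][1])
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated row ids in ", path, ": ", paste(dup, collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric counts in ", path)
  rownames(m) <- ids
  if (orientation == "auto") {
    orientation <- if (corner %in% c("otu", "otu_id", "#otu id", "otuid",
                                     "taxon", "taxon_id", "species"))
      "otus_rows"
    else
      "samples_rows"
  }
  if (orientation == "otus_rows") m <- t(m)
  otu_table(m)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] and enforces the invariants the downstream
#' phylogenetic-turnover statistics need: at least two uniquely labelled
#' tips and non-negative branch lengths on every edge.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick file ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse Newick file ", path)
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object to validate.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2L) stop("tree has fewer than 2 tips")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicated tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  tree
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `site_id`, `longitude` and `latitude`;
#' all remaining numeric columns are treated as environmental variables
#' (missing values allowed, kept as `NA`).
#'
#' @param path path to a TSV file.
#' @return a data.frame keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                     comment.char = "#", stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta data.frame to validate.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "site_id", "longitude", "latitude")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) stop("duplicated sample ids: ", paste(dup, collapse = ", "))
  if (any(!is.finite(meta$latitude)) || any(abs(meta$latitude) > 90))
    stop("latitude out of [-90, 90]")
  if (any(!is.finite(meta$longitude)) || any(abs(meta$longitude) > 180))
    stop("longitude out of [-180, 180]")
  rownames(meta) <- meta$sample_id
  meta
}

#' Environmental variable columns of a metadata table
#'
#' Numeric columns other than coordinates and identifiers.
#'
#' @param meta metadata data.frame.
#' @return character vector of column names.
#' @export
env_variables <- function(meta) {
  cand <- setdiff(names(meta), c("sample_id", "site_id", "longitude",
                                 "latitude", "position_km"))
  cand[vapply(meta[cand], is.numeric, logical(1))]
}

#' Harmonize OTU table, phylogeny and metadata
#'
#' Restricts OTUs to the intersection of table columns and tree tips (the
#' tree is pruned with [ape::keep.tip()], which preserves patristic distances
#' between retained tips), and samples to those present in the metadata.
#' Every dropped OTU or sample is logged via `message()`. Harmonization is
#' idempotent.
#'
#' @param table OTU table (samples x OTUs).
#' @param tree phylogeny covering (some of) the OTUs.
#' @param meta sample metadata.
#' @return list with elements `table`, `tree`, `meta`.
#' @export
harmonize <- function(table, tree, meta) {
  table <- validate_otu_table(table)
  tree <- validate_phylogeny(tree)
  meta <- validate_sample_metadata(meta)
  keep_otu <- intersect(colnames(table), tree$tip.label)
  if (length(keep_otu) < 2L)
    stop("fewer than 2 OTUs shared between table and tree")
  drop_otu <- setdiff(colnames(table), keep_otu)
  drop_tip <- setdiff(tree$tip.label, keep_otu)
  if (length(drop_otu))
    log_msg("dropping ", length(drop_otu), " table OTU(s) absent from tree: ",
            paste(utils::head(drop_otu, 5), collapse = ", "),
            if (length(drop_otu) > 5) ", ...")
  if (length(drop_tip))
    log_msg("pruning ", length(drop_tip), " tree tip(s) absent from table: ",
            paste(utils::head(drop_tip, 5), collapse = ", "),
            if (length(drop_tip) > 5) ", ...")
  if (length(drop_tip)) tree <- ape::keep.tip(tree, keep_otu)
  keep_s <- intersect(rownames(table), meta$sample_id)
  if (!length(keep_s)) stop("no samples shared between table and metadata")
  drop_s <- setdiff(rownames(table), keep_s)
  if (length(drop_s))
    log_msg("dropping ", length(drop_s), " sample(s) without metadata: ",
            paste(utils::head(drop_s, 5), collapse = ", "),
            if (length(drop_s) > 5) ", ...")
  drop_m <- setdiff(meta$sample_id, keep_s)
  if (length(drop_m))
    log_msg("dropping ", length(drop_m), " metadata row(s) without counts")
  table <- table[keep_s, keep_otu, drop = FALSE]
  meta <- meta[keep_s, , drop = FALSE]
  list(table = otu_table(table), tree = tree, meta = meta)
}

#' Rarefy an OTU table to even depth
#'
#' Each sample is subsampled uniformly without replacement (multivariate
#' hypergeometric) to exactly `depth` reads; samples whose total is below
#' `depth` are dropped and logged. The default depth of 20,005 reads follows
#' the rarefaction level used throughout the package's reference analyses
#' of agricultural soil communities.
#'
#' @param table OTU table.
#' @param depth target reads per sample (default 20005).
#' @param seed integer seed; the whole operation is reproducible given
#'   (`table`, `depth`, `seed`).
#' @return rarefied [otu_table()] (possibly with fewer samples).
#' @export
rarefy_table <- function(table, depth = 20005L, seed = 1L) {
  table <- validate_otu_table(table)
  if (depth < 1L) stop("depth must be >= 1")
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  if (any(!keep))
    log_msg("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(utils::head(rownames(table)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ...")
  out <- table[keep, , drop = FALSE]
  set.seed(as.integer(seed))
  for (s in seq_len(nrow(out))) {
    x <- out[s, ]
    if (sum(x) == depth) next
    pool <- rep.int(seq_along(x), x)
    pick <- sample(pool, depth, replace = FALSE)
    out[s, ] <- tabulate(pick, nbins = length(x))
  }
  otu_table(out)
}

#' Aggregate plot-level samples to site composites
#'
#' One composite profile per site: the mean of the plots' relative-abundance
#' vectors, rescaled to sum to one (averaging proportions rather than raw
#' counts keeps unequal sequencing depth from weighting plots unevenly).
#' Site metadata are the means of coordinates and numeric environmental
#' variables across the site's plots.
#'
#' @param table OTU table (plots x OTUs).
#' @param meta plot metadata carrying `site_id`.
#' @return list with `table` (sites x OTUs relative abundances, a numeric
#'   matrix -- not an `otu_table` since entries are proportions) and `meta`
#'   (one row per site).
#' @export
aggregate_by_site <- function(table, meta) {
  table <- validate_otu_table(table)
  meta <- validate_sample_metadata(meta)
  common <- intersect(rownames(table), meta$sample_id)
  if (!length(common)) stop("no samples shared between table and metadata")
  table <- table[common, , drop = FALSE]
  meta <- meta[common, , drop = FALSE]
  rel <- sweep(table, 1, rowSums(table), "/")
  sites <- unique(meta$site_id)
  prof <- matrix(0, length(sites), ncol(table),
                 dimnames = list(sites, colnames(table)))
  for (k in seq_along(sites)) {
    rows <- which(meta$site_id == sites[k])
    p <- colMeans(rel[rows, , drop = FALSE])
    prof[k, ] <- p / sum(p)
  }
  num <- names(meta)[vapply(meta, is.numeric, logical(1))]
  smeta <- data.frame(sample_id = sites, site_id = sites,
                      stringsAsFactors = FALSE)
  for (v in num)
    smeta[[v]] <- vapply(sites, function(s)
      mean(meta[[v]][meta$site_id == s], na.rm = TRUE), numeric(1))
  rownames(smeta) <- sites
  list(table = prof, meta = smeta)
}

#' Write a matrix or data.frame as TSV with a provenance header
#'
#' @param x matrix or data.frame.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @param rownames_title column title for row names when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NULL, rownames_title = "id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# assemblyscales ",
                    as.character(utils::packageVersion("assemblyscales")),
                    if (!is.null(seed)) paste0(" seed=", seed)), con)
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- rownames_title
    x <- df
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
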