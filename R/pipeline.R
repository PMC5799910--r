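#' Build a validated pipeline configuration
#'
#' All knobs of the end-to-end analysis in one declarative object. Exactly
#' one of `simulate` (arguments for [simulate_dataset()]) or `input`
#' (list with paths `table`, `tree`, `meta`) must be supplied. Unknown
#' keys in either sub-list are rejected.
#'
#' @param simulate named list of [simulate_dataset()] arguments, or `NULL`.
#' @param input named list of input paths (`table`, `tree`, `meta`), or
#'   `NULL`.
#' @param rarefy_depth rarefaction depth; `NULL` skips rarefaction.
#' @param bnti_on_rarefied compute phylogenetic turnover on the rarefied
#'   table (default) or on the raw counts.
#' @param n_null randomizations for the turnover nulls.
#' @param weighted abundance-weighted turnover statistics.
#' @param n_bins number of spatial-scale bins.
#' @param bands small/medium/large thresholds in km.
#' @param sad_samples fit rank-abundance models on at most this many
#'   samples (0 disables the stage).
#' @param sad_zsm include the neutral zero-sum multinomial fit.
#' @param varpart_aggregate_sites partition variance at site level.
#' @param env_vars environmental columns for Mantel/varpart; `NULL` = all.
#' @param seed master seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL,
                            rarefy_depth = NULL, bnti_on_rarefied = TRUE,
                            n_null = 999L, weighted = TRUE, n_bins = 16L,
                            bands = c(250, 800), sad_samples = 10L,
                            sad_zsm = TRUE, varpart_aggregate_sites = TRUE,
                            env_vars = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(input))
    stop("supply exactly one of 'simulate' or 'input'")
  if (!is.null(simulate)) {
    bad <- setdiff(names(simulate), names(formals(simulate_dataset)))
    if (length(bad)) stop("unknown simulate keys: ", paste(bad, collapse = ", "))
  }
  if (!is.null(input)) {
    bad <- setdiff(names(input), c("table", "tree", "meta"))
    if (length(bad)) stop("unknown input keys: ", paste(bad, collapse = ", "))
    miss <- setdiff(c("table", "tree", "meta"), names(input))
    if (length(miss)) stop("input missing: ", paste(miss, collapse = ", "))
  }
  if (n_null < 99L) stop("n_null must be >= 99")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (!is.null(rarefy_depth) && rarefy_depth < 1) stop("rarefy_depth must be >= 1")
  structure(list(simulate = simulate, input = input,
                 rarefy_depth = rarefy_depth,
                 bnti_on_rarefied = bnti_on_rarefied,
                 n_null = as.integer(n_null), weighted = weighted,
                 n_bins = as.integer(n_bins), bands = bands,
                 sad_samples = as.integer(sad_samples), sad_zsm = sad_zsm,
                 varpart_aggregate_sites = varpart_aggregate_sites,
                 env_vars = env_vars, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file's top-level keys are the arguments of [pipeline_config()];
#' unknown keys are rejected before any computation.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full scale-resolved assembly analysis
#'
#' Executes the stages in dependency order -- data (simulate or ingest +
#' harmonize), rarefaction, alpha/beta diversity and distance decay,
#' phylogenetic turnover nulls (ses.MNTD, betaNTI), spatial-scale binning
#' with the per-scale process table and Kruskal-Wallis test, rank-abundance
#' model comparison, and PCNM-integrated variance partitioning -- writing
#' per-stage TSV/JSON outputs, a `summary.json`, the resolved configuration
#' and a `MANIFEST.tsv` with content hashes. Any stage error aborts the run
#' naming the stage; outputs written so far stay on disk.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))
  smry <- list(seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dat <- stage("data", {
    if (!is.null(config$simulate)) {
      sim <- do.call(simulate_dataset,
                     modifyList(config$simulate, list(seed = config$seed)))
      write_synthetic_dataset(sim, file.path(out_dir, "inputs"))
      sim
    } else {
      harmonize(read_otu_table(config$input$table),
                read_newick(config$input$tree),
                read_sample_metadata(config$input$meta))
    }
  })
  dat <- stage("harmonize", harmonize(dat$table, dat$tree, dat$meta))
  table_raw <- dat$table

  table_ana <- stage("rarefy", {
    if (is.null(config$rarefy_depth)) table_raw
    else rarefy_table(table_raw, config$rarefy_depth, seed = config$seed + 11L)
  })
  if (!is.null(config$rarefy_depth) && !identical(dim(table_ana), dim(table_raw)))
    dat <- harmonize(table_ana, dat$tree, dat$meta)
  meta <- dat$meta; tree <- dat$tree
  table_ana <- table_ana[rownames(table_ana) %in% meta$sample_id, ,
                         drop = FALSE]

  stage("diversity", {
    alpha <- alpha_diversity(table_ana, tree)
    write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"),
              seed = config$seed)
    bc <- bray_curtis_matrix(table_ana)
    G <- geodesic_matrix(meta)
    vars <- if (is.null(config$env_vars)) env_variables(meta) else config$env_vars
    ed <- tryCatch(suppressWarnings(env_distance(meta, vars)),
                   error = function(e) NULL)
    if (!is.null(ed) && identical(rownames(ed), rownames(bc))) {
      mt <- mantel_test(bc, ed, n_perm = 999L, seed = config$seed + 21L)
      smry$mantel_env <- mt
    }
    dd <- distance_decay(1 - bc, G)
    smry$distance_decay <- dd
    cors <- tryCatch(suppressWarnings(alpha_env_correlation(alpha, meta, vars)),
                     error = function(e) NULL)
    if (!is.null(cors))
      write_tsv(cors, file.path(out_dir, "alpha_env_correlation.tsv"))
    invisible(NULL)
  })

  bnti <- stage("bnti", {
    tb <- if (config$bnti_on_rarefied) table_ana else table_raw
    D <- patristic_matrix(tree)
    ses <- ses_mntd(tb, D, n_null = config$n_null, seed = config$seed + 31L,
                    weighted = config$weighted)
    write_tsv(ses, file.path(out_dir, "ses_mntd.tsv"), seed = config$seed)
    B <- beta_nti(tb, D, n_null = config$n_null, seed = config$seed + 32L,
                  weighted = config$weighted)
    write_tsv(beta_nti_pairs(B), file.path(out_dir, "beta_nti_pairs.tsv"),
              seed = config$seed)
    write_tsv(B$beta_nti, file.path(out_dir, "beta_nti_matrix.tsv"),
              rownames_title = "sample_id")
    cls <- classify_pairs(B)
    smry$ses_mntd_median <- median(ses$ses, na.rm = TRUE)
    smry$pct_stochastic <- 100 * mean(cls$label == "stochastic")
    smry$median_bnti <- median(cls$beta_nti)
    B
  })

  stage("scales", {
    G <- geodesic_matrix(meta)
    bins <- bin_pairs(G, n_bins = config$n_bins)
    st <- scale_table(bnti, bins, bands = config$bands)
    write_tsv(as.data.frame(st)[, c("scale", "distance_km", "median_bnti",
                                    "deterministic_pct", "stochastic_pct",
                                    "n_pairs", "band")],
              file.path(out_dir, "scale_table.tsv"), seed = config$seed)
    smry$scale_table <- as.data.frame(st)
    if (sum(st$n_pairs > 0) >= 2)
      smry$kruskal_wallis <- kruskal_wallis_scales(bnti, bins)
    invisible(NULL)
  })

  if (config$sad_samples > 0) stage("sad", {
    take <- utils::head(rownames(table_ana), config$sad_samples)
    models <- c(if (config$sad_zsm) "zsm", "brokenstick", "preemption",
                "lognormal", "zipf", "mandelbrot")
    rows <- list()
    for (s in take) {
      tab <- compare_models(table_ana[s, ], models = models)
      rows[[s]] <- cbind(sample_id = s, tab)
    }
    sad <- do.call(rbind, rows)
    write_tsv(sad, file.path(out_dir, "sad_models.tsv"), seed = config$seed)
    best <- vapply(rows, function(r) r$model[1], character(1))
    smry$sad_best_tally <- as.list(table(best))
    invisible(NULL)
  })

  stage("varpart", {
    if (config$varpart_aggregate_sites) {
      agg <- aggregate_by_site(table_ana, meta)
      vtab <- agg$table; vmeta <- agg$meta
    } else {
      vtab <- table_ana; vmeta <- meta
    }
    vars <- if (is.null(config$env_vars)) env_variables(vmeta) else config$env_vars
    E <- scale(as.matrix(vmeta[, vars, drop = FALSE]))
    E <- E[, apply(E, 2, function(z) all(is.finite(z))), drop = FALSE]
    G <- geodesic_matrix(vmeta)
    sp <- pcnm_axes(G)
    Y <- transform_response(vtab, "hellinger")
    vp <- partition_three(Y, env = E, trend = vmeta$latitude, spatial = sp)
    jsonlite::write_json(vp[setdiff(names(vp), "blocks")],
                         file.path(out_dir, "varpart.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(as.data.frame(vp), file.path(out_dir, "varpart.tsv"))
    smry$varpart <- vp[c("pure_env", "pure_trend", "pure_spatial",
                             "shared_all", "residual", "adj_total")]
    invisible(NULL)
  })

  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- setdiff(list.files(out_dir, recursive = TRUE), "MANIFEST.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(smry)
}
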