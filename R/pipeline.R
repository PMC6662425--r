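#' Default pipeline configuration
#'
#' @param genotypes Path to a VCF or 0/1/2 matrix file.
#' @param metadata Path to the sample-metadata CSV.
#' @param occurrences Optional path to an occurrence-record CSV; when
#'   `NULL` the range-expansion stage is skipped.
#' @param out_dir Output directory.
#' @param format Genotype file format (`"auto"`, `"vcf"`, `"matrix012"`).
#' @param max_missing_fraction Individual-missingness filter; default 0.75.
#' @param min_presence_fraction Locus-presence filter; default 0.10.
#' @param maf_threshold Rare-variant MAF threshold; default 0.10.
#' @param K_range Candidate cluster counts; default `1:5`.
#' @param n_permutations Permutations for AMOVA and r-bar-d; default 199.
#' @param seed Master seed (mandatory: every stochastic stage derives its
#'   seed from it).
#' @param grid_spacing,span Introduction-inference parameters.
#' @param compute_surface Krige per peeling round; default `FALSE`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, metadata, occurrences = NULL,
                            out_dir = "selfspread_out", format = "auto",
                            max_missing_fraction = 0.75,
                            min_presence_fraction = 0.10,
                            maf_threshold = 0.10,
                            K_range = 1:5, n_permutations = 199,
                            seed = 1L, grid_spacing = 0.05, span = 0.75,
                            compute_surface = FALSE) {
  cfg <- as.list(environment())
  stopifnot(max_missing_fraction > 0, max_missing_fraction <= 1,
            min_presence_fraction > 0, min_presence_fraction <= 1,
            maf_threshold > 0, maf_threshold <= 0.5,
            length(K_range) >= 1, !is.null(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the invasion-history pipeline end to end
#'
#' Stage order: read + filter (individuals before loci) -> diversity and
#' mating-system summary per cluster -> AMOVA (when metadata carries >= 2
#' localities) -> index of association -> PCA -> admixture with K
#' selection -> introduction inference by iterative peeling -> (when
#' occurrence records are supplied) range expansion and lag-phase test.
#' Per-stage TSV/JSON outputs and a machine-readable manifest (package
#' version, seed, thresholds, input checksums) are written to
#' `config$out_dir`. Any stage error aborts with a stage-named message;
#' outputs of completed stages are retained.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file whose
#'   keys mirror its arguments).
#' @return Invisible list with per-stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message("[", name, "] done in ",
            sprintf("%.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  out <- list()

  out$filtered <- stage("filter", {
    g <- read_genotypes(cfg$genotypes, cfg$format)
    g <- filter_individuals_by_missingness(g, cfg$max_missing_fraction)
    g <- filter_loci_by_presence(g, cfg$min_presence_fraction)
    write_genotypes(g, file.path(cfg$out_dir, "genotypes_filtered.tsv"))
    g
  })
  g <- out$filtered
  md <- stage("metadata", {
    md <- read_metadata(cfg$metadata)
    missing <- setdiff(g$samples, md$sample)
    if (length(missing)) {
      stop("no metadata for sample(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    md
  })

  out$pca <- stage("pca", {
    p <- pca_genotypes(g, n_components = min(10, n_samples(g) - 1, n_loci(g)))
    utils::write.table(
      data.frame(sample = rownames(p$scores), p$scores),
      file.path(cfg$out_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(explained = p$explained),
                         file.path(cfg$out_dir, "pca_explained.json"),
                         digits = 10)
    p
  })

  out$k_selection <- stage("select_k", {
    ks <- select_k(g, K_range = cfg$K_range,
                   seeds = cfg$seed + 0:2)
    jsonlite::write_json(list(K = ks$K, curve = ks$curve),
                         file.path(cfg$out_dir, "k_selection.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "columns")
    ks
  })

  out$admixture <- stage("admixture", {
    fit <- estimate_admixture(g, out$k_selection$K, seed = cfg$seed)
    utils::write.table(
      data.frame(sample = rownames(fit$Q), round(fit$Q, 6)),
      file.path(cfg$out_dir, "admixture_Q.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    fit
  })
  clusters <- stats::setNames(
    colnames(out$admixture$Q)[max.col(out$admixture$Q, ties.method = "first")],
    g$samples)

  out$diversity <- stage("diversity", {
    ds <- diversity_summary(g, clusters)
    utils::write.table(ds, file.path(cfg$out_dir, "diversity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ds
  })

  loc <- stats::setNames(md$site[match(g$samples, md$sample)], g$samples)
  reg <- stats::setNames(md$ecoregion[match(g$samples, md$sample)], g$samples)
  out$amova <- stage("amova", {
    if (length(unique(loc)) < 2) {
      message("single locality; AMOVA skipped")
      NULL
    } else {
      reg_use <- if (length(unique(reg)) >= 2) reg else NULL
      am <- amova(g, loc, reg_use, n_permutations = cfg$n_permutations,
                  seed = cfg$seed + 11)
      utils::write.table(am$table, file.path(cfg$out_dir, "amova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      am
    }
  })

  out$linkage <- stage("index_of_association", {
    ia <- rbar_d(g, n_permutations = cfg$n_permutations,
                 seed = cfg$seed + 23)
    jsonlite::write_json(
      ia[c("rbar_d", "Ia", "V_O", "V_E", "p_value", "n_permutations")],
      file.path(cfg$out_dir, "rbar_d.json"), auto_unbox = TRUE, digits = 10)
    ia
  })

  out$introductions <- stage("introductions", {
    inf <- iterative_peeling(g, md, clusters,
                             maf_threshold = cfg$maf_threshold,
                             span = cfg$span,
                             compute_surface = cfg$compute_surface,
                             grid_spacing = cfg$grid_spacing)
    utils::write.table(inf$order,
                       file.path(cfg$out_dir, "introduction_order.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (rd in inf$rounds) {
      utils::write.table(
        rd$density,
        file.path(cfg$out_dir, sprintf("rare_density_round%d.tsv", rd$round)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(rd$surface)) {
        utils::write.table(
          rd$surface$grid,
          file.path(cfg$out_dir, sprintf("kriging_round%d.tsv", rd$round)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    inf
  })

  if (!is.null(cfg$occurrences)) {
    out$expansion <- stage("range_expansion", {
      occ <- read_occurrences(cfg$occurrences)
      grid <- bin_records(occ)
      curve <- accumulation_curve(grid)
      fit <- lag_phase_regression(curve)
      utils::write.table(curve,
                         file.path(cfg$out_dir, "accumulation_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(slope = fit$slope, intercept = fit$intercept,
             r_squared = fit$r_squared, f_statistic = fit$f_statistic,
             df = fit$df, p_value = fit$p_value, n_years = fit$n_years,
             lag_comparison = fit$lag_comparison),
        file.path(cfg$out_dir, "lag_phase.json"),
        auto_unbox = TRUE, digits = 10)
      list(grid = grid, curve = curve, fit = fit)
    })
  } else {
    message("no occurrence records supplied; range-expansion stage skipped")
  }

  out$manifest <- stage("manifest", {
    inputs <- c(genotypes = cfg$genotypes, metadata = cfg$metadata,
                occurrences = if (is.null(cfg$occurrences)) NULL else cfg$occurrences)
    manifest <- list(
      package = "selfspread",
      version = as.character(utils::packageVersion("selfspread")),
      seed = cfg$seed,
      thresholds = list(max_missing_fraction = cfg$max_missing_fraction,
                        min_presence_fraction = cfg$min_presence_fraction,
                        maf_threshold = cfg$maf_threshold),
      K_range = cfg$K_range,
      n_permutations = cfg$n_permutations,
      input_checksums = as.list(tools::md5sum(inputs)),
      stages = names(Filter(Negate(is.null), out))
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    manifest
  })
  invisible(out)
}
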