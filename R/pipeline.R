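#' Run the full evaluation pipeline and write all stage outputs
#'
#' Orchestrates: read (or generate) the trait table, aggregate replicate
#' means, fold changes against the stressed control, MEI, membership
#' normalization, comprehensive scores with ranking/CV/optimum, the
#' trait-structure analyses (Pearson correlation, PCA, UPGMA dendrogram on
#' the trait vectors), and — when Ct data are supplied or generated —
#' relative expression by 2^-dCt. All stage outputs are written as CSV (6
#' significant digits), the dendrogram as Newick, and a machine-readable
#' JSON report (full precision) plus a plain-text summary.
#'
#' Exactly one of `input` (a trait CSV path or `trait_table`) and `config`
#' (a [generator_config()]) must be supplied.
#'
#' @param input path to a trait CSV, or a `trait_table` data frame.
#' @param config a `generator_config` to simulate from instead.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded in the report and used for generation.
#' @param directions trait direction vector (default [trait_directions()]);
#'   may also be a path to a YAML/JSON override file.
#' @param ct_input optional Ct CSV path or `ct_table`; ignored when
#'   `config` carries a Ct block (which is then generated).
#' @param reference_gene reference gene for expression quantification
#'   (default: the config's Ct-block reference).
#' @inheritParams membership
#' @return A `run_report` list (also written to `report.json`): stage file
#'   paths, the `u_score_report`, optimum dose, warnings, package version
#'   and configuration echo.
#' @export
run_pipeline <- function(input = NULL, config = NULL, out_dir = "mitieval_out",
                         seed = NULL,
                         directions = trait_directions(),
                         direction_mode = c("oriented", "literal"),
                         scope = c("per-genotype", "pooled"),
                         ct_input = NULL, reference_gene = NULL) {
  direction_mode <- match.arg(direction_mode)
  scope <- match.arg(scope)
  if (is.null(input) == is.null(config)) {
    abort("mitieval_config_error",
          "supply exactly one of input (trait table) and config (generator)")
  }
  if (is.character(directions) && length(directions) == 1 &&
      is.null(names(directions))) {
    directions <- read_direction_override(directions)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  tab <- if (!is.null(config)) {
    g <- generate_trait_table(config, seed = seed)
    paths$trait_table <- file.path(out_dir, "trait_table.csv")
    write_trait_table(g, paths$trait_table)
    g
  } else if (is.character(input)) {
    read_trait_table(input)
  } else {
    validate_trait_table(as.data.frame(input))
  }

  means <- aggregate_means(tab)
  paths$means <- file.path(out_dir, "means.csv")
  write_stage_csv(means, paths$means)

  fc <- withCallingHandlers(
    fold_change(means, reference = "CK-", zero_reference = "drop"),
    warning = function(w) { note(w); invokeRestart("muffleWarning") }
  )
  paths$fold_change <- file.path(out_dir, "fold_change.csv")
  write_stage_csv(fc, paths$fold_change)

  mei <- withCallingHandlers(
    compute_mei(means, directions = directions),
    warning = function(w) { note(w); invokeRestart("muffleWarning") }
  )
  paths$mei <- file.path(out_dir, "mei.csv")
  write_mei_table(mei, paths$mei)

  u <- membership(mei, direction_mode = direction_mode, scope = scope)
  paths$membership <- file.path(out_dir, "membership.csv")
  write_stage_csv(as.data.frame(u), paths$membership)

  report <- comprehensive_score(u)
  paths$scores <- file.path(out_dir, "scores.csv")
  write_stage_csv(report$scores, paths$scores)

  # trait-structure stage on the cell-mean matrix (trait vectors as points)
  tm <- trait_matrix(means)
  cr <- pearson_matrix(tm)
  paths$correlation_r <- file.path(out_dir, "correlation_r.csv")
  paths$correlation_p <- file.path(out_dir, "correlation_p.csv")
  utils::write.csv(signif(cr$r, 6), paths$correlation_r)
  utils::write.csv(signif(cr$p, 6), paths$correlation_p)
  pca <- trait_pca(tm)
  paths$pca_eigenvalues <- file.path(out_dir, "pca_eigenvalues.csv")
  write_stage_csv(data.frame(
    pc = seq_along(pca$eigenvalues), eigenvalue = pca$eigenvalues,
    variance_pct = pca$variance_percent,
    cumulative_pct = pca$cumulative_percent,
    retained = seq_along(pca$eigenvalues) %in% pca$retained
  ), paths$pca_eigenvalues)
  paths$pca_loadings <- file.path(out_dir, "pca_loadings.csv")
  utils::write.csv(signif(pca$loadings, 6), paths$pca_loadings)
  dn <- upgma_cluster(t(tm))
  paths$dendrogram_newick <- file.path(out_dir, "dendrogram.nwk")
  write_newick(dn, paths$dendrogram_newick)
  paths$dendrogram_merges <- file.path(out_dir, "dendrogram_merges.csv")
  write_stage_csv(dn$merges, paths$dendrogram_merges)

  # expression stage
  expr_summary <- NULL
  ct <- if (!is.null(config) && !is.null(config$ct_block)) {
    generate_ct_table(config, seed = if (is.null(seed)) NULL else seed + 1L)
  } else if (is.character(ct_input)) {
    read_ct_table(ct_input)
  } else if (!is.null(ct_input)) {
    validate_ct_table(as.data.frame(ct_input))
  }
  if (!is.null(ct)) {
    refg <- reference_gene %||%
      (if (!is.null(config)) config$ct_block$reference_gene else NULL)
    if (is.null(refg)) {
      abort("mitieval_config_error",
            "reference_gene required with external Ct input")
    }
    expr <- relative_expression(ct, reference_gene = refg)
    paths$expression <- file.path(out_dir, "expression.csv")
    write_stage_csv(expr$cells, paths$expression)
    expr_summary <- list(reference_gene = refg, cells = nrow(expr$cells))
  }

  run <- list(
    package_version = as.character(utils::packageVersion("mitieval")),
    seed = seed,
    direction_mode = direction_mode,
    scope = scope,
    optimum = report$optimum,
    cv_percent_of_u = report$cv,
    u_scores = report$scores,
    treatment_means = report$treatment_means,
    scope_audit = attr(u, "scope_record"),
    significant_trait_pairs = cr$significant_pairs,
    pca_retained = pca$retained,
    expression = expr_summary,
    warnings = warnings_log,
    paths = paths,
    config_echo = if (!is.null(config)) {
      list(replicates = config$replicates, cv_percent = config$cv_percent,
           distribution = config$distribution)
    } else list(input = if (is.character(input)) input else "<in-memory>")
  )
  class(run) <- "run_report"
  jsonlite::write_json(unclass(run), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(utils::capture.output(print(run)),
             file.path(out_dir, "report.txt"))
  invisible(run)
}

write_stage_csv <- function(x, path) {
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], signif, digits = 6)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("mitieval pipeline run (version", x$package_version, ")\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  cat("  mode:", x$direction_mode, "/", x$scope, "\n\n")
  cat("Mean comprehensive score by treatment:\n")
  print(x$treatment_means, row.names = FALSE, digits = 4)
  cat(sprintf("\nOptimum: %s (%.1f mg/L 5-HT), mean U = %.3f\n",
              x$optimum$treatment, x$optimum$dose_mg_per_L, x$optimum$mean_u))
  cat(sprintf("CV of U: %.1f%%; significant trait pairs: %d; retained PCs: %s\n",
              x$cv_percent_of_u, x$significant_trait_pairs,
              paste(x$pca_retained, collapse = ", ")))
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}
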