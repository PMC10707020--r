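#' Membership-function normalization of MEI values
#'
#' Min-max rescaling of the mitigation effect index within each trait's
#' scope, the staple normalization of fuzzy-set comprehensive evaluation in
#' crop stress studies:
#' \deqn{U_{i,Tn} = \frac{MEI_{i,Tn} - MEI_{i,min}}{MEI_{i,max} - MEI_{i,min}}}
#' where min and max are taken over all dose treatments in the scope.
#'
#' Two direction conventions are offered. In the default `"oriented"` mode
#' the formula above applies to every trait: the MEI itself is already
#' oriented (larger = stronger mitigation) by the direction switch in
#' [compute_mei()], so a second inversion would undo it. In `"literal"` mode
#' negatively correlated traits are additionally inverted
#' (\eqn{U' = 1 - U}), matching a literal reading of the membership-function
#' pair in which negative traits use the complementary form.
#'
#' @param mei a `mei_table` from [compute_mei()].
#' @param direction_mode `"oriented"` (default) or `"literal"`; see Details.
#' @param scope `"per-genotype"` (default): min/max per (genotype, trait)
#'   across its dose treatments; `"pooled"`: per trait across both genotypes'
#'   dose treatments.
#' @param degenerate `"error"` (default) when all MEIs in a scope are equal
#'   (zero range), or `"midpoint"` to assign U = 0.5 with a warning.
#' @param directions named direction vector; defaults to the one recorded in
#'   `mei` (needed for `"literal"` mode only).
#' @return Data frame of class `membership_table` with columns `genotype`,
#'   `treatment`, `trait`, `u`, and a `scope_record` attribute listing, per
#'   scope, the extreme MEIs and the cells that attained them.
#' @export
membership <- function(mei, direction_mode = c("oriented", "literal"),
                       scope = c("per-genotype", "pooled"),
                       degenerate = c("error", "midpoint"),
                       directions = attr(mei, "directions")) {
  direction_mode <- match.arg(direction_mode)
  scope <- match.arg(scope)
  degenerate <- match.arg(degenerate)
  x <- as.data.frame(mei)
  grp <- if (scope == "per-genotype") {
    cell_key(x$genotype, x$trait)
  } else {
    x$trait
  }
  if (direction_mode == "literal") {
    if (is.null(directions)) {
      abort("mitieval_registry_error",
            "literal mode needs trait directions; none recorded or supplied")
    }
    miss <- setdiff(unique(x$trait), names(directions))
    if (length(miss)) {
      abort("mitieval_registry_error",
            sprintf("no direction for trait(s): %s",
                    paste(miss, collapse = ", ")))
    }
  }
  u <- numeric(nrow(x))
  recs <- list()
  for (g in unique(grp)) {
    i <- grp == g
    v <- x$mei[i]
    if (sum(i) < 2) {
      abort("mitieval_degenerate_scope_error",
            sprintf("scope for trait %s has < 2 cells", x$trait[i][1]))
    }
    rng <- range(v)
    if (rng[2] - rng[1] == 0) {
      if (degenerate == "error") {
        abort("mitieval_degenerate_scope_error",
              sprintf("constant MEI within scope (trait %s%s): min = max = %g",
                      x$trait[i][1],
                      if (scope == "per-genotype")
                        paste0(", genotype ", x$genotype[i][1]) else "",
                      rng[1]))
      }
      warn("mitieval_degenerate_scope_warning",
           sprintf("constant MEI within scope (trait %s): assigning U = 0.5",
                   x$trait[i][1]))
      u[i] <- 0.5
    } else {
      u[i] <- (v - rng[1]) / (rng[2] - rng[1])
    }
    recs[[g]] <- data.frame(
      trait = x$trait[i][1],
      genotype = if (scope == "per-genotype") x$genotype[i][1] else NA,
      mei_min = rng[1], mei_max = rng[2],
      min_cell = cell_key(x$genotype[i][which.min(v)],
                          x$treatment[i][which.min(v)]),
      max_cell = cell_key(x$genotype[i][which.max(v)],
                          x$treatment[i][which.max(v)]),
      stringsAsFactors = FALSE
    )
  }
  if (direction_mode == "literal") {
    negs <- x$trait %in% names(directions)[directions == "negative"]
    u[negs] <- 1 - u[negs]
  }
  out <- data.frame(genotype = x$genotype, treatment = x$treatment,
                    trait = x$trait, u = u, stringsAsFactors = FALSE)
  sr <- do.call(rbind, recs)
  rownames(sr) <- NULL
  attr(out, "scope_record") <- sr
  attr(out, "direction_mode") <- direction_mode
  attr(out, "scope") <- scope
  class(out) <- c("membership_table", "data.frame")
  out
}

#' Comprehensive mitigation score per (genotype, treatment) cell
#'
#' The comprehensive score U_Tn is the unweighted arithmetic mean of the
#' trait-wise membership values of a cell (1/17 of their sum in the full
#' 17-trait evaluation). Each cell must carry the complete trait set; the
#' per-treatment mean across genotypes, descending rank, coefficient of
#' variation over all cells, and optimum treatment are derived from it.
#'
#' @param u a `membership_table` from [membership()].
#' @return An object of class `u_score_report`: a list with `scores`
#'   (genotype, treatment, u), `treatment_means` (treatment, dose, mean_u,
#'   rank), `cv` (percent, over all genotype x treatment cells), `optimum`
#'   (see [select_optimum()]), `n_traits`.
#' @export
comprehensive_score <- function(u) {
  x <- as.data.frame(u)
  traits <- sort(unique(x$trait))
  key <- cell_key(x$genotype, x$treatment)
  for (k in unique(key)) {
    have <- x$trait[key == k]
    absent <- setdiff(traits, have)
    if (length(absent)) {
      i <- which(key == k)[1]
      abort("mitieval_missing_trait_error",
            sprintf("cell (%s, %s) lacks trait(s): %s",
                    x$genotype[i], x$treatment[i],
                    paste(absent, collapse = ", ")))
    }
  }
  agg <- aggregate(x$u, list(genotype = x$genotype, treatment = x$treatment),
                   mean)
  names(agg)[3] <- "u"
  agg <- agg[order(agg$genotype, agg$treatment), , drop = FALSE]
  rownames(agg) <- NULL
  tm <- aggregate(agg$u, list(treatment = agg$treatment), mean)
  names(tm)[2] <- "mean_u"
  tm$dose_mg_per_L <- treatment_dose(tm$treatment)
  tm$rank <- rank(-tm$mean_u, ties.method = "min")
  tm <- tm[order(tm$rank, tm$treatment),
           c("treatment", "dose_mg_per_L", "mean_u", "rank")]
  rownames(tm) <- NULL
  rep <- list(
    scores = agg,
    treatment_means = tm,
    cv = coefficient_of_variation(agg$u),
    n_traits = length(traits),
    direction_mode = attr(u, "direction_mode"),
    scope = attr(u, "scope")
  )
  class(rep) <- "u_score_report"
  rep$optimum <- select_optimum(rep)
  rep
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation.
#'
#' @param x numeric vector with at least 2 values and positive mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(0.4, 0.6)) # ~28.28
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) {
    abort("mitieval_cv_error", "CV needs at least 2 values")
  }
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    abort("mitieval_cv_error",
          sprintf("CV undefined: mean = %g is not positive", m))
  }
  100 * stats::sd(x) / m
}

#' Select the optimum treatment from a comprehensive-score report
#'
#' The treatment with the maximal mean comprehensive score across genotypes.
#' Exact ties are reported as a set, never broken arbitrarily; the margin is
#' the gap between the best and the best non-tied runner-up.
#'
#' @param report a `u_score_report`, or its `treatment_means` data frame.
#' @return List with `treatment`, `dose_mg_per_L`, `mean_u`, `margin`,
#'   `ties` (character vector of all argmax treatments, length > 1 on a tie).
#' @export
select_optimum <- function(report) {
  tm <- if (inherits(report, "u_score_report")) report$treatment_means
        else report
  best <- max(tm$mean_u)
  ties <- sort(tm$treatment[tm$mean_u == best])
  rest <- tm$mean_u[tm$mean_u < best]
  list(
    treatment = ties[1],
    dose_mg_per_L = unname(treatment_dose(ties[1])),
    mean_u = best,
    margin = if (length(rest)) best - max(rest) else NA_real_,
    ties = ties
  )
}

#' @export
print.u_score_report <- function(x, ...) {
  cat("Comprehensive mitigation evaluation (", x$n_traits, " traits, ",
      x$direction_mode %||% "oriented", " mode, ",
      x$scope %||% "per-genotype", " scope)\n\n", sep = "")
  cat("Mean comprehensive score by treatment:\n")
  print(x$treatment_means, row.names = FALSE, digits = 4)
  opt <- x$optimum
  cat(sprintf("\nOptimum: %s (%.1f mg/L), mean U = %.3f, margin %.3f\n",
              paste(opt$ties, collapse = " = "), opt$dose_mg_per_L,
              opt$mean_u, opt$margin))
  if (length(opt$ties) > 1) cat("  (exact tie among:",
                                paste(opt$ties, collapse = ", "), ")\n")
  cat(sprintf("CV of U over %d cells: %.1f%%\n", nrow(x$scores), x$cv))
  invisible(x)
}
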