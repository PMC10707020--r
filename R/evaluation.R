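#' Multi-trait mitigation-effect evaluation
#'
#' Fits the full comprehensive evaluation to a replicate-level trait table:
#' replicates are aggregated to cell means, the mitigation effect index (MEI)
#' is computed per genotype, dose treatment and trait against the unstressed
#' (`CK+`) and stressed (`CK-`) controls, MEIs are normalized to [0, 1] by
#' the membership function within each trait's scope, and the comprehensive
#' score U_Tn is the unweighted mean of the membership values of each
#' (genotype, treatment) cell. Treatments are ranked on the mean U across
#' genotypes and the optimum dose selected.
#'
#' @param x a `trait_table` data frame (long format: genotype, treatment,
#'   replicate, trait, value), e.g. from [read_trait_table()] or
#'   [generate_trait_table()].
#' @param directions named trait -> direction vector
#'   (default [trait_directions()]).
#' @inheritParams membership
#' @param mei_degenerate policy for a degenerate stress gap, see
#'   [compute_mei()].
#' @return An object of class `mitigation_eval` with components `means`,
#'   `mei`, `membership`, `report` (a `u_score_report`), and the call.
#' @seealso [compute_mei()], [membership()], [comprehensive_score()]
#' @examples
#' tab <- generate_trait_table(deepseed_preset(cv_percent = 0), seed = 1)
#' fit <- mitigation_eval(tab)
#' fit
#' coef(fit)
#' @export
mitigation_eval <- function(x, directions = trait_directions(),
                            direction_mode = c("oriented", "literal"),
                            scope = c("per-genotype", "pooled"),
                            mei_degenerate = c("error", "drop"),
                            degenerate = c("error", "midpoint")) {
  direction_mode <- match.arg(direction_mode)
  scope <- match.arg(scope)
  means <- aggregate_means(x)
  mei <- compute_mei(means, directions = directions,
                     degenerate = match.arg(mei_degenerate))
  u <- membership(mei, direction_mode = direction_mode, scope = scope,
                  degenerate = match.arg(degenerate))
  rep <- comprehensive_score(u)
  structure(
    list(means = means, mei = mei, membership = u, report = rep,
         directions = directions, direction_mode = direction_mode,
         scope = scope, call = match.call()),
    class = "mitigation_eval"
  )
}

#' @export
print.mitigation_eval <- function(x, ...) {
  cat("Multi-trait mitigation-effect evaluation\n")
  cat("  genotypes:  ", paste(unique(x$means$genotype), collapse = ", "), "\n")
  cat("  traits:     ", length(unique(x$mei$trait)), "\n")
  cat("  treatments: ", paste(unique(x$mei$treatment), collapse = ", "), "\n\n")
  print(x$report)
  invisible(x)
}

#' @export
summary.mitigation_eval <- function(object, ...) {
  sc <- object$report$scores
  wide <- stats::reshape(sc, idvar = "genotype", timevar = "treatment",
                         direction = "wide")
  names(wide) <- sub("^u\\.", "", names(wide))
  structure(
    list(fit = object, u_by_cell = wide,
         mei_range = range(object$mei$mei),
         scope_record = attr(object$membership, "scope_record")),
    class = "summary.mitigation_eval"
  )
}

#' @export
print.summary.mitigation_eval <- function(x, ...) {
  print(x$fit)
  cat("\nComprehensive score U per genotype x treatment:\n")
  print(x$u_by_cell, row.names = FALSE, digits = 3)
  cat(sprintf("\nMEI range: [%.3f, %.3f]\n",
              x$mei_range[1], x$mei_range[2]))
  invisible(x)
}

#' Comprehensive scores of a fitted evaluation
#'
#' @param object a `mitigation_eval` object.
#' @param ... unused.
#' @return Named numeric vector of per-cell comprehensive scores U, names
#'   `genotype:treatment`.
#' @export
coef.mitigation_eval <- function(object, ...) {
  sc <- object$report$scores
  stats::setNames(sc$u, paste(sc$genotype, sc$treatment, sep = ":"))
}

#' Plot the comprehensive mitigation scores
#'
#' Grouped bar plot of U per treatment, one bar group per genotype, with the
#' across-genotype mean overlaid.
#'
#' @param x a `mitigation_eval` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mitigation_eval <- function(x, ...) {
  sc <- x$report$scores
  m <- tapply(sc$u, list(sc$genotype, sc$treatment), mean)
  bp <- graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                          ylab = "comprehensive score U",
                          xlab = "treatment",
                          legend.text = rownames(m), ...)
  graphics::points(colMeans(bp), colMeans(m), pch = 19)
  invisible(bp)
}
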