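#' Mitigation effect index (MEI) per genotype, treatment and trait
#'
#' For each trait i and dose treatment Tn (T1--T5), the MEI measures how far
#' the treatment moves the trait from its stressed-control value, scaled by
#' the absolute stress-induced gap between the two controls:
#' \deqn{MEI_{i,Tn} = \frac{T_{i,Tn} - T_{i,CK-}}{|T_{i,CK+} - T_{i,CK-}|}}
#' for traits positively correlated with deep-seeding tolerance, and
#' \deqn{MEI_{i,Tn} = \frac{T_{i,CK-} - T_{i,Tn}}{|T_{i,CK+} - T_{i,CK-}|}}
#' for negatively correlated traits, where the T's are treatment-level cell
#' means. The direction switch guarantees that a larger MEI always means a
#' stronger mitigation effect. MEI is 0 exactly when the treatment equals the
#' stressed control, 1 when it restores the trait across the full stress gap;
#' values outside [0, 1] are legitimate and not clipped.
#'
#' @param means a `trait_means` data frame (see [aggregate_means()]).
#' @param directions named character vector trait -> `"positive"`/`"negative"`
#'   (default [trait_directions()]).
#' @param degenerate what to do when the stress gap `|CK+ - CK-|` is at or
#'   below `tol`: `"error"` (default) or `"drop"` the trait with a warning.
#' @param tol denominator tolerance; default
#'   `1e-12 * max(|CK+|, |CK-|, 1)` per (genotype, trait).
#' @return A data frame of class `mei_table` with columns `genotype`,
#'   `treatment`, `trait`, `mei`, plus a `provenance` attribute holding the
#'   anchor means (`ck_plus`, `ck_minus`) and cell mean `t_value` used.
#' @examples
#' m <- data.frame(
#'   genotype = "g", treatment = c("CK+", "CK-", "T4"),
#'   trait = "seedling_weight", mean = c(1, 0.423, 2.42 * 0.423),
#'   sd = NA, n = 1
#' )
#' compute_mei(m, directions = c(seedling_weight = "positive"))
#' @export
compute_mei <- function(means, directions = trait_directions(),
                        degenerate = c("error", "drop"), tol = NULL) {
  degenerate <- match.arg(degenerate)
  traits <- unique(means$trait)
  miss_dir <- setdiff(traits, names(directions))
  if (length(miss_dir)) {
    abort("mitieval_registry_error",
          sprintf("no tolerance direction for trait(s): %s",
                  paste(miss_dir, collapse = ", ")))
  }
  genotypes <- unique(means$genotype)
  tns <- intersect(dose_treatments(), unique(means$treatment))
  if (!length(tns)) {
    abort("mitieval_missing_cell_error", "no dose treatments (T1-T5) in means")
  }
  rows <- vector("list", length(genotypes) * length(traits))
  k <- 0L
  for (g in genotypes) {
    for (tr in traits) {
      ckp <- get_cell_mean(means, g, "CK+", tr)
      ckm <- get_cell_mean(means, g, "CK-", tr)
      denom <- abs(ckp - ckm)
      tol_gt <- tol %||% (1e-12 * max(abs(ckp), abs(ckm), 1))
      if (denom <= tol_gt) {
        if (degenerate == "error") {
          abort("mitieval_degenerate_denominator_error",
                sprintf(paste0("stress gap |CK+ - CK-| degenerate for ",
                               "genotype %s, trait %s (|%.3g - %.3g| <= %.3g)"),
                        g, tr, ckp, ckm, tol_gt))
        }
        warn("mitieval_degenerate_denominator_warning",
             sprintf("dropping trait %s (genotype %s): degenerate stress gap",
                     tr, g))
        next
      }
      tv <- vapply(tns, function(tn) get_cell_mean(means, g, tn, tr), 0)
      num <- if (directions[[tr]] == "positive") tv - ckm else ckm - tv
      k <- k + 1L
      rows[[k]] <- data.frame(
        genotype = g, treatment = tns, trait = tr, mei = num / denom,
        ck_plus = ckp, ck_minus = ckm, t_value = tv,
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) {
    abort("mitieval_degenerate_denominator_error",
          "all traits dropped: no MEI computable")
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  prov <- out[c("genotype", "treatment", "trait",
                "ck_plus", "ck_minus", "t_value")]
  out <- out[c("genotype", "treatment", "trait", "mei")]
  attr(out, "provenance") <- prov
  attr(out, "directions") <- directions[intersect(names(directions), traits)]
  class(out) <- c("mei_table", "data.frame")
  out
}

#' Write an MEI table and its provenance sidecar
#'
#' @param x a `mei_table` from [compute_mei()].
#' @param path output CSV path; the anchor means go to a JSON sidecar at
#'   `sub(".csv", "_provenance.json", path)`.
#' @return `path`, invisibly.
#' @export
write_mei_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("genotype", "treatment", "trait", "mei")],
                   path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", "_provenance.json", path)
  jsonlite::write_json(attr(x, "provenance"), side, digits = NA)
  invisible(path)
}
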