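#' Read a long-format trait table from CSV
#'
#' The file must have the header `genotype,treatment,replicate,trait,value`.
#' Treatment codes are validated against [treatment_registry()]; trait names
#' against `traits` (default: the 17-trait registry). Duplicate
#' (genotype, treatment, replicate, trait) keys, non-numeric values and
#' out-of-range proportion traits are rejected.
#'
#' @param path CSV file path.
#' @param traits character vector of admissible trait names, or `NULL` to
#'   accept any.
#' @return A validated data frame of class `trait_table`.
#' @seealso [write_trait_table()], [validate_trait_table()]
#' @export
read_trait_table <- function(path, traits = trait_registry()$trait) {
  if (!file.exists(path)) {
    abort("mitieval_io_error", sprintf("file not found: %s", path))
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(
                         genotype = "character", treatment = "character",
                         trait = "character"
                       )[character(0)])
  validate_trait_table(x, traits = traits)
}

#' Validate a long-format trait table
#'
#' @param x data frame with columns `genotype`, `treatment`, `replicate`,
#'   `trait`, `value`.
#' @inheritParams read_trait_table
#' @return `x` with class `trait_table` prepended.
#' @export
validate_trait_table <- function(x, traits = trait_registry()$trait) {
  need <- c("genotype", "treatment", "replicate", "trait", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort("mitieval_schema_error",
          sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  x <- x[need]
  if (!is.numeric(x$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$value))) & !is.na(x$value))
    abort("mitieval_parse_error",
          sprintf("non-numeric value at row(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (anyNA(x$value) || any(!is.finite(x$value))) {
    abort("mitieval_parse_error",
          sprintf("non-finite value at row(s): %s",
                  paste(utils::head(which(!is.finite(x$value)), 5),
                        collapse = ", ")))
  }
  bad_trt <- setdiff(unique(x$treatment), treatment_codes())
  if (length(bad_trt)) {
    abort("mitieval_schema_error",
          sprintf("unknown treatment code(s): %s",
                  paste(bad_trt, collapse = ", ")))
  }
  if (!is.null(traits)) {
    bad_tr <- setdiff(unique(x$trait), traits)
    if (length(bad_tr)) {
      abort("mitieval_schema_error",
            sprintf("unknown trait(s): %s", paste(bad_tr, collapse = ", ")))
    }
    reg <- trait_registry()
    prop <- reg$trait[reg$is_proportion]
    p <- x$trait %in% prop
    if (any(p) && (any(x$value[p] < 0) || any(x$value[p] > 100))) {
      abort("mitieval_schema_error",
            "proportion trait values must lie in [0, 100] (percent scale)")
    }
  }
  key <- cell_key(x$genotype, x$treatment, x$replicate, x$trait)
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE][1, ]
    abort("mitieval_duplication_error",
          sprintf("duplicate observation key: %s / %s / rep %s / %s",
                  d$genotype, d$treatment, d$replicate, d$trait))
  }
  class(x) <- c("trait_table", "data.frame")
  x
}

#' Write a trait table to CSV
#'
#' Values are written in full precision (`format(..., digits = 15)` is not
#' used; `write.csv` default formatting keeps up to 15 significant digits),
#' so a read/write round-trip preserves observations to numerical identity
#' for values with at most 6 significant decimal digits.
#'
#' @param x a `trait_table` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate replicate observations to cell means
#'
#' Computes, per (genotype, treatment, trait) cell, the arithmetic mean, the
#' sample standard deviation (n - 1 denominator; `NA` when n = 1) and the
#' replicate count. The treatment-level evaluation (MEI, membership) operates
#' on these cell means.
#'
#' @param x a `trait_table` data frame.
#' @return A data frame of class `trait_means` with columns `genotype`,
#'   `treatment`, `trait`, `mean`, `sd`, `n`.
#' @export
aggregate_means <- function(x) {
  x <- validate_trait_table(as.data.frame(x), traits = NULL)
  f <- list(genotype = x$genotype, treatment = x$treatment, trait = x$trait)
  out <- aggregate(x$value, f, FUN = mean)
  names(out)[4] <- "mean"
  out$sd <- aggregate(x$value, f, FUN = function(v) {
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })$x
  out$n <- aggregate(x$value, f, FUN = length)$x
  out <- out[order(out$genotype, out$treatment, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trait_means", "data.frame")
  out
}

# fetch a single cell mean, error if absent
get_cell_mean <- function(means, genotype, treatment, trait) {
  i <- means$genotype == genotype & means$treatment == treatment &
    means$trait == trait
  if (!any(i)) {
    abort("mitieval_missing_cell_error",
          sprintf("missing cell: genotype %s, treatment %s, trait %s",
                  genotype, treatment, trait))
  }
  means$mean[i][1]
}

#' Fold changes of cell means against a reference treatment
#'
#' For every (genotype, trait) and non-reference treatment, the ratio
#' mean(treatment) / mean(reference). This is the reporting convention of
#' dose-response seedling studies ("x times that of the stressed control").
#'
#' @param means a `trait_means` data frame from [aggregate_means()].
#' @param reference reference treatment code (e.g. `"CK-"`).
#' @param zero_reference `"error"` (default) to fail on a zero reference
#'   mean, or `"drop"` to omit such (genotype, trait) ratios with a warning
#'   (a stressed-control emergence rate of exactly 0 is a legitimate cell).
#' @return Data frame `genotype`, `treatment`, `trait`, `ratio`.
#' @export
fold_change <- function(means, reference = "CK-",
                        zero_reference = c("error", "drop")) {
  zero_reference <- match.arg(zero_reference)
  if (!reference %in% means$treatment) {
    abort("mitieval_missing_cell_error",
          sprintf("reference treatment %s absent from means", reference))
  }
  ref <- means[means$treatment == reference, c("genotype", "trait", "mean")]
  names(ref)[3] <- "ref_mean"
  x <- means[means$treatment != reference,
             c("genotype", "treatment", "trait", "mean")]
  m <- merge(x, ref, by = c("genotype", "trait"), all.x = TRUE)
  if (anyNA(m$ref_mean)) {
    k <- m[is.na(m$ref_mean), ][1, ]
    abort("mitieval_missing_cell_error",
          sprintf("missing reference cell: genotype %s, trait %s",
                  k$genotype, k$trait))
  }
  if (any(m$ref_mean == 0)) {
    k <- m[m$ref_mean == 0, ][1, ]
    if (zero_reference == "error") {
      abort("mitieval_division_error",
            sprintf("zero reference mean: genotype %s, trait %s (ref %s)",
                    k$genotype, k$trait, reference))
    }
    warn("mitieval_division_warning",
         sprintf("dropping ratios with zero reference mean (e.g. %s / %s)",
                 k$genotype, k$trait))
    m <- m[m$ref_mean != 0, , drop = FALSE]
  }
  m$ratio <- m$mean / m$ref_mean
  out <- m[order(m$genotype, m$treatment, m$trait),
           c("genotype", "treatment", "trait", "ratio")]
  rownames(out) <- NULL
  out
}
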