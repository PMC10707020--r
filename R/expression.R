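#' Read a qPCR Ct table from CSV
#'
#' Expected header: `genotype,treatment,tissue,gene,replicate,ct`.
#'
#' @param path CSV file path.
#' @return Validated data frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) {
    abort("mitieval_io_error", sprintf("file not found: %s", path))
  }
  validate_ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a Ct table
#'
#' @param x data frame with columns `genotype`, `treatment`, `tissue`,
#'   `gene`, `replicate`, `ct`.
#' @return `x` with class `ct_table` prepended.
#' @export
validate_ct_table <- function(x) {
  need <- c("genotype", "treatment", "tissue", "gene", "replicate", "ct")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort("mitieval_schema_error",
          sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(x$ct) || any(!is.finite(x$ct))) {
    abort("mitieval_parse_error", "Ct values must be finite numbers")
  }
  class(x) <- c("ct_table", "data.frame")
  x
}

#' Relative gene expression by the 2^-dCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference) within the same
#' (genotype, treatment, tissue, replicate), and relative expression is
#' 2^-dCt, so expression is exactly 1 when target and reference amplify at
#' the same cycle and halves for every extra cycle of the target. Replicate
#' handling follows the `average` argument: `"expression"` (default)
#' computes expression per replicate and then averages; `"ct"` averages dCt
#' across replicates first and exponentiates once (the two differ by
#' Jensen's inequality).
#'
#' @param ct a `ct_table` data frame.
#' @param reference_gene identifier of the internal reference gene.
#' @param average `"expression"` or `"ct"`; see Details.
#' @return List of class `expression_table` with `replicates` (per-replicate
#'   expression, `average = "expression"` only) and `cells` (per
#'   (genotype, treatment, tissue, gene) mean expression).
#' @examples
#' ct <- data.frame(genotype = "g", treatment = "CK+", tissue = "mesocotyl",
#'                  gene = c("ref", "tgt"), replicate = 1, ct = c(20, 25))
#' relative_expression(ct, reference_gene = "ref")$cells$expression # 2^-5
#' @export
relative_expression <- function(ct, reference_gene,
                                average = c("expression", "ct")) {
  average <- match.arg(average)
  x <- validate_ct_table(as.data.frame(ct))
  if (!reference_gene %in% x$gene) {
    abort("mitieval_pairing_error",
          sprintf("reference gene %s absent from table", reference_gene))
  }
  ref <- x[x$gene == reference_gene,
           c("genotype", "treatment", "tissue", "replicate", "ct")]
  names(ref)[5] <- "ref_ct"
  tgt <- x[x$gene != reference_gene, , drop = FALSE]
  m <- merge(tgt, ref, by = c("genotype", "treatment", "tissue", "replicate"),
             all.x = TRUE)
  if (anyNA(m$ref_ct)) {
    k <- m[is.na(m$ref_ct), ][1, ]
    abort("mitieval_pairing_error",
          sprintf("no reference Ct for (%s, %s, %s, rep %s)",
                  k$genotype, k$treatment, k$tissue, k$replicate))
  }
  m$dct <- m$ct - m$ref_ct
  m$expression <- 2^(-m$dct)
  grp <- list(genotype = m$genotype, treatment = m$treatment,
              tissue = m$tissue, gene = m$gene)
  cells <- if (average == "expression") {
    aggregate(m$expression, grp, mean)
  } else {
    tmp <- aggregate(m$dct, grp, mean)
    tmp$x <- 2^(-tmp$x)
    tmp
  }
  names(cells)[5] <- "expression"
  cells <- cells[order(cells$genotype, cells$treatment, cells$tissue,
                       cells$gene), , drop = FALSE]
  rownames(cells) <- NULL
  structure(
    list(
      replicates = if (average == "expression") {
        m[order(m$genotype, m$treatment, m$tissue, m$gene, m$replicate),
          c("genotype", "treatment", "tissue", "gene", "replicate",
            "dct", "expression")]
      } else NULL,
      cells = cells,
      reference_gene = reference_gene,
      average = average
    ),
    class = "expression_table"
  )
}

#' Correlate gene expression with physiological trait means
#'
#' Matches expression cells and trait cell means on (genotype, treatment)
#' for one tissue and computes the Pearson correlation (r and two-sided p
#' from the t-distribution, via [pearson_matrix()]) for every gene x trait
#' pair, flagging significance at p < 0.05.
#'
#' @param expr an `expression_table` from [relative_expression()].
#' @param means a `trait_means` data frame.
#' @param tissue tissue to analyse (`"mesocotyl"` or `"coleoptile"`).
#' @param traits trait names to correlate against (default: the IAA and
#'   lignin traits of the given tissue).
#' @return Data frame `gene`, `trait`, `r`, `p`, `n`, `significant`.
#' @export
expression_trait_correlation <- function(expr, means, tissue,
                                         traits = NULL) {
  if (is.null(traits)) {
    suff <- if (tissue == "mesocotyl") "mesocotyl" else "coleoptile"
    traits <- paste0(c("iaa_", "lignin_"), suff)
  }
  ec <- expr$cells[expr$cells$tissue == tissue, , drop = FALSE]
  if (!nrow(ec)) {
    abort("mitieval_insufficient_data_error",
          sprintf("no expression cells for tissue %s", tissue))
  }
  ew <- stats::reshape(ec[c("genotype", "treatment", "gene", "expression")],
                       idvar = c("genotype", "treatment"), timevar = "gene",
                       direction = "wide")
  genes <- sub("^expression\\.", "", names(ew)[-(1:2)])
  names(ew)[-(1:2)] <- genes
  tmn <- means[means$trait %in% traits,
               c("genotype", "treatment", "trait", "mean")]
  tw <- stats::reshape(tmn, idvar = c("genotype", "treatment"),
                       timevar = "trait", direction = "wide")
  names(tw)[-(1:2)] <- sub("^mean\\.", "", names(tw)[-(1:2)])
  mm <- merge(ew, tw, by = c("genotype", "treatment"))
  if (nrow(mm) < 3) {
    abort("mitieval_insufficient_data_error",
          sprintf("only %d matched (genotype, treatment) cells; need >= 3",
                  nrow(mm)))
  }
  mat <- as.matrix(mm[, c(genes, intersect(traits, names(mm))), drop = FALSE])
  cr <- pearson_matrix(mat)
  tr_in <- intersect(traits, colnames(mat))
  out <- expand.grid(gene = genes, trait = tr_in,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- cr$r[cbind(out$gene, out$trait)]
  out$p <- cr$p[cbind(out$gene, out$trait)]
  out$n <- nrow(mm)
  out$significant <- !is.na(out$p) & out$p < 0.05
  out
}
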