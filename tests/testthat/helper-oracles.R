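# Independent brute-force oracles, deliberately written as plain loops over
# the defining formulas, sharing no code with the package internals.

# MEI by direct evaluation of the defining ratio
oracle_mei <- function(ck_plus, ck_minus, t_value, direction) {
  num <- if (direction == "positive") t_value - ck_minus else ck_minus - t_value
  num / abs(ck_plus - ck_minus)
}

# min-max membership, cell by cell, over a trait x treatment MEI matrix
oracle_membership <- function(mei_mat) {
  u <- mei_mat
  for (i in seq_len(nrow(mei_mat))) {
    lo <- min(mei_mat[i, ]); hi <- max(mei_mat[i, ])
    for (j in seq_len(ncol(mei_mat))) {
      u[i, j] <- (mei_mat[i, j] - lo) / (hi - lo)
    }
  }
  u
}

# full chain for one genotype: means is trait x treatment matrix whose first
# two columns are the CK+ and CK- anchors; returns U per dose treatment
oracle_chain_u <- function(means, directions) {
  doses <- colnames(means)[-(1:2)]
  mei <- matrix(NA_real_, nrow(means), length(doses),
                dimnames = list(rownames(means), doses))
  for (i in seq_len(nrow(means))) {
    for (j in seq_along(doses)) {
      mei[i, j] <- oracle_mei(means[i, 1], means[i, 2], means[i, doses[j]],
                              directions[rownames(means)[i]])
    }
  }
  u <- oracle_membership(mei)
  colMeans(u)
}

# Pearson r by the explicit sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# long-format toy trait table built from a cell-mean array, exact replicates
toy_table <- function(means_by_cell, replicates = 2, jitter = 0) {
  rows <- list()
  k <- 0
  for (g in dimnames(means_by_cell)[[1]])
    for (trt in dimnames(means_by_cell)[[2]])
      for (tr in dimnames(means_by_cell)[[3]]) {
        for (r in seq_len(replicates)) {
          k <- k + 1
          off <- if (jitter > 0) stats::rnorm(1, 0, jitter) else 0
          rows[[k]] <- data.frame(
            genotype = g, treatment = trt, replicate = r, trait = tr,
            value = means_by_cell[g, trt, tr] + off
          )
        }
      }
  do.call(rbind, rows)
}

# random (valid) trait table over arbitrary trait names
random_trait_table <- function(n_genotypes = 2, traits = c("tr_a", "tr_b"),
                               treatments = c("CK+", "CK-", "T1", "T4"),
                               replicates = 3) {
  g <- paste0("g", seq_len(n_genotypes))
  out <- expand.grid(genotype = g, treatment = treatments,
                     replicate = seq_len(replicates), trait = traits,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- round(stats::runif(nrow(out), 0.5, 50), 4)
  out
}
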