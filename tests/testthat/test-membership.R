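mei_table_from <- function(mat, genotype = "g1") {
  # mat: trait x treatment matrix of MEI values
  x <- expand.grid(trait = rownames(mat), treatment = colnames(mat),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  x$genotype <- genotype
  x$mei <- mat[cbind(x$trait, x$treatment)]
  out <- x[c("genotype", "treatment", "trait", "mei")]
  class(out) <- c("mei_table", "data.frame")
  out
}

test_that("membership is the min-max identity on {0, 0.5, 1}", {
  mat <- matrix(c(0, 0.5, 1), 1, dimnames = list("tr_a", c("T1", "T2", "T3")))
  u <- membership(mei_table_from(mat))
  expect_equal(u$u[order(u$treatment)], c(0, 0.5, 1))
})

test_that("constant MEI scope errors by default, midpoint by policy", {
  mat <- matrix(c(0.3, 0.3), 1, dimnames = list("tr_a", c("T1", "T2")))
  expect_error(membership(mei_table_from(mat)),
               class = "mitieval_degenerate_scope_error")
  expect_warning(u <- membership(mei_table_from(mat), degenerate = "midpoint"),
                 class = "mitieval_degenerate_scope_warning")
  expect_equal(u$u, c(0.5, 0.5))
})

test_that("membership matches cell-by-cell brute-force re-evaluation", {
  set.seed(51)
  for (rep in 1:5) {
    mat <- matrix(rnorm(6), 2, 3,
                  dimnames = list(c("tr_a", "tr_b"), c("T1", "T2", "T3")))
    u <- membership(mei_table_from(mat))
    want <- oracle_membership(mat)
    expect_equal(u$u, want[cbind(u$trait, u$treatment)], ignore_attr = TRUE)
    expect_true(all(u$u >= 0 & u$u <= 1))
  }
})

test_that("per trait, the scope minimum maps to 0 and the maximum to 1", {
  set.seed(52)
  mat <- matrix(rnorm(15), 3, 5,
                dimnames = list(paste0("tr_", 1:3), dose_treatments()))
  u <- membership(mei_table_from(mat))
  for (tr in rownames(mat)) {
    ui <- u$u[u$trait == tr]
    expect_equal(min(ui), 0)
    expect_equal(max(ui), 1)
  }
  rec <- attr(u, "scope_record")
  expect_equal(sort(rec$trait), sort(rownames(mat)))
  expect_equal(rec$mei_min, apply(mat, 1, min)[rec$trait], ignore_attr = TRUE)
})

test_that("literal mode inverts negative-direction traits only", {
  mat <- matrix(c(0, 1, 0, 1), 2, byrow = TRUE,
                dimnames = list(c("pos_tr", "neg_tr"), c("T1", "T2")))
  mei <- mei_table_from(mat)
  attr(mei, "directions") <- c(pos_tr = "positive", neg_tr = "negative")
  u_or <- membership(mei, direction_mode = "oriented")
  u_li <- membership(mei, direction_mode = "literal")
  expect_equal(u_li$u[u_li$trait == "pos_tr"], u_or$u[u_or$trait == "pos_tr"])
  expect_equal(u_li$u[u_li$trait == "neg_tr"],
               1 - u_or$u[u_or$trait == "neg_tr"])
})

test_that("pooled scope takes extremes across genotypes", {
  m1 <- mei_table_from(matrix(c(0, 1), 1,
                              dimnames = list("tr_a", c("T1", "T2"))), "g1")
  m2 <- mei_table_from(matrix(c(2, 3), 1,
                              dimnames = list("tr_a", c("T1", "T2"))), "g2")
  both <- rbind(m1, m2)
  class(both) <- c("mei_table", "data.frame")
  u <- membership(both, scope = "pooled")
  expect_equal(u$u[u$genotype == "g1"][order(u$treatment[u$genotype == "g1"])],
               c(0, 1) / 3)
  u_per <- membership(both, scope = "per-genotype")
  expect_equal(sort(u_per$u[u_per$genotype == "g2"]), c(0, 1))
})

test_that("comprehensive score is the mean membership of each cell", {
  set.seed(53)
  mat <- matrix(runif(15), 3, 5,
                dimnames = list(paste0("tr_", 1:3), dose_treatments()))
  u <- membership(mei_table_from(mat))
  rep <- comprehensive_score(u)
  # brute-force: sum / n per treatment column of the membership matrix
  want <- colMeans(oracle_membership(mat))
  got <- setNames(rep$scores$u, rep$scores$treatment)
  expect_equal(got[names(want)], want)
  expect_true(all(rep$scores$u >= 0 & rep$scores$u <= 1))

  # all-ones cell scores exactly 1
  ones <- u; ones$u <- 1
  class(ones) <- class(u)
  expect_true(all(comprehensive_score(ones)$scores$u == 1))
})

test_that("comprehensive score is invariant to trait order and flags absentees", {
  set.seed(54)
  mat <- matrix(runif(10), 2, 5,
                dimnames = list(c("tr_a", "tr_b"), dose_treatments()))
  u <- membership(mei_table_from(mat))
  shuf <- u[sample(nrow(u)), ]
  class(shuf) <- class(u)
  expect_equal(comprehensive_score(shuf)$scores,
               comprehensive_score(u)$scores)

  holey <- u[!(u$trait == "tr_b" & u$treatment == "T3"), ]
  class(holey) <- class(u)
  expect_error(comprehensive_score(holey), "tr_b",
               class = "mitieval_missing_trait_error")
})

test_that("raising one MEI cannot lower its cell's comprehensive score", {
  set.seed(55)
  mat <- matrix(runif(15), 3, 5,
                dimnames = list(paste0("tr_", 1:3), dose_treatments()))
  base <- comprehensive_score(membership(mei_table_from(mat)))
  u0 <- setNames(base$scores$u, base$scores$treatment)
  for (j in colnames(mat)) {
    m2 <- mat
    m2["tr_1", j] <- m2["tr_1", j] + 0.5
    bumped <- comprehensive_score(membership(mei_table_from(m2)))
    u1 <- setNames(bumped$scores$u, bumped$scores$treatment)
    expect_gte(u1[j] - u0[j], -1e-12)
  }
})

test_that("coefficient of variation follows the percent sample-sd definition", {
  expect_equal(coefficient_of_variation(c(0.5, 0.5, 0.5)), 0)
  expect_equal(coefficient_of_variation(c(0.4, 0.6)),
               100 * sd(c(0.4, 0.6)) / 0.5)
  expect_equal(coefficient_of_variation(c(0.4, 0.6)), 28.28, tolerance = 1e-3)
  # scale invariance
  set.seed(56)
  v <- runif(8, 0.1, 1)
  expect_equal(coefficient_of_variation(3.7 * v), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(0.4), class = "mitieval_cv_error")
  expect_error(coefficient_of_variation(c(-1, 0.5)),
               class = "mitieval_cv_error")
})

test_that("optimum selection is an argmax with honest tie reporting", {
  tm <- data.frame(treatment = c("T1", "T4", "T5"),
                   mean_u = c(0.2, 0.65, 0.3))
  opt <- select_optimum(tm)
  expect_equal(opt$treatment, "T4")
  expect_equal(opt$dose_mg_per_L, 2.5)
  expect_equal(opt$margin, 0.35)
  expect_equal(opt$ties, "T4")

  tie <- data.frame(treatment = c("T2", "T3", "T4"),
                    mean_u = c(0.1, 0.6, 0.6))
  opt2 <- select_optimum(tie)
  expect_equal(opt2$ties, c("T3", "T4"))
  expect_equal(opt2$margin, 0.5)
})

test_that("full index-to-score chain matches a brute-force oracle on toys", {
  set.seed(57)
  dirs <- c(tr_1 = "positive", tr_2 = "negative", tr_3 = "positive")
  for (rep in 1:5) {
    means <- matrix(runif(15, 1, 10), 3, 5,
                    dimnames = list(names(dirs),
                                    c("CK+", "CK-", "T1", "T2", "T3")))
    long <- expand.grid(genotype = "g1", treatment = colnames(means),
                        replicate = 1, trait = rownames(means),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    long$value <- means[cbind(long$trait, long$treatment)]
    fit <- mitigation_eval(long, directions = dirs)
    want <- oracle_chain_u(means, dirs)
    got <- coef(fit)
    expect_equal(unname(got[paste0("g1:", names(want))]), unname(want),
                 tolerance = 1e-12)
  }
})
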