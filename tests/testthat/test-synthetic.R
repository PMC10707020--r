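test_that("the generator is deterministic under a fixed seed", {
  cfg <- deepseed_preset()
  expect_identical(generate_trait_table(cfg, seed = 7),
                   generate_trait_table(cfg, seed = 7))
  expect_false(identical(generate_trait_table(cfg, seed = 7),
                         generate_trait_table(cfg, seed = 8)))
  expect_identical(generate_ct_table(cfg, seed = 7),
                   generate_ct_table(cfg, seed = 7))
})

test_that("noise-free replicates equal their cell means exactly", {
  tab <- generate_trait_table(deepseed_preset(cv_percent = 0), seed = 1)
  m <- aggregate_means(tab)
  expect_true(all(m$sd == 0))
  # the full pipeline on this table is deterministic
  f1 <- mitigation_eval(tab)
  f2 <- mitigation_eval(generate_trait_table(deepseed_preset(cv_percent = 0),
                                             seed = 99))
  expect_equal(coef(f1), coef(f2))
})

test_that("derived length traits satisfy their identities in every replicate", {
  tab <- generate_trait_table(deepseed_preset(cv_percent = 15), seed = 5)
  w <- stats::reshape(
    tab[tab$trait %in% c("mesocotyl_length", "coleoptile_length",
                         "total_length", "mc_ratio"), ],
    idvar = c("genotype", "treatment", "replicate"), timevar = "trait",
    direction = "wide"
  )
  names(w) <- sub("^value\\.", "", names(w))
  expect_equal(w$total_length, w$mesocotyl_length + w$coleoptile_length)
  expect_equal(w$mc_ratio, w$mesocotyl_length / w$coleoptile_length)
})

test_that("the preset reproduces the calibrated ratios at zero noise", {
  tab <- generate_trait_table(deepseed_preset(cv_percent = 0), seed = 1)
  m <- aggregate_means(tab)
  suppressWarnings(fc <- fold_change(m, "CK-", zero_reference = "drop"))
  rat <- function(g, trt, tr) fc$ratio[fc$genotype == g &
                                         fc$treatment == trt & fc$trait == tr]
  # dose ratios vs the stressed control
  expect_equal(rat("ly119-2", "T4", "seedling_weight"), 2.42)
  expect_equal(rat("ZRX87-1", "T4", "seedling_weight"), 2.03)
  expect_equal(rat("ly119-2", "T3", "seedling_length"), 2.21)
  expect_equal(rat("ly119-2", "T4", "h2o2_mesocotyl"), 1 - 0.6749)
  expect_equal(rat("ZRX87-1", "T4", "h2o2_coleoptile"), 1 - 0.5542)
  expect_equal(rat("ly119-2", "T4", "lignin_mesocotyl"), 1 - 0.5682)
  expect_equal(rat("ly119-2", "T4", "mesocotyl_length"), 1.891)
  expect_equal(rat("ZRX87-1", "T4", "coleoptile_length"), 1.868)
  expect_equal(rat("ly119-2", "T3", "mesocotyl_coarse"), 1 + 2.809)
  # stress ratios vs the unstressed control
  fcp <- fold_change(m, "CK+", zero_reference = "drop")
  ratp <- function(g, trt, tr) fcp$ratio[fcp$genotype == g &
                                           fcp$treatment == trt &
                                           fcp$trait == tr]
  expect_equal(ratp("ly119-2", "CK-", "seedling_weight"), 1 - 0.577)
  expect_equal(ratp("ZRX87-1", "CK-", "seedling_weight"), 1 - 0.258)
  expect_equal(ratp("ly119-2", "CK-", "iaa_mesocotyl"), 2.81)
  expect_equal(ratp("ZRX87-1", "CK-", "h2o2_mesocotyl"), 4.21)
  expect_equal(ratp("ly119-2", "CK-", "mesocotyl_length"), 4.92)
  # derived stressed-control ratios follow from the solved baselines
  expect_equal(ratp("ly119-2", "CK-", "total_length"), 2.80, tolerance = 1e-12)
  expect_equal(ratp("ly119-2", "CK-", "mc_ratio"), 4.92 / 1.48,
               tolerance = 1e-12)
  # emergence rates are stored as absolute percentages
  mm <- m[m$trait == "emergence_rate" & m$genotype == "ly119-2", ]
  expect_equal(setNames(mm$mean, mm$treatment)[c("CK-", "T3", "T4")],
               c("CK-" = 0, "T3" = 60, "T4" = 95))
})

test_that("unprinted preset cells are tagged interpolated, assumed cells tagged", {
  cfg <- deepseed_preset()
  cm <- cfg$cell_means
  # fully printed dose profiles carry no interpolation tags
  expect_false(any(cm$interpolated[cm$trait == "seedling_weight"]))
  expect_false(any(cm$interpolated[cm$trait == "h2o2_mesocotyl"]))
  # anchored traits: the printed-best cell is exact, the other doses tagged
  ml <- cm[cm$genotype == "ly119-2" & cm$trait == "mesocotyl_length", ]
  expect_false(ml$interpolated[ml$treatment == "T4"])
  expect_true(all(ml$interpolated[ml$treatment %in% c("T1", "T2", "T3", "T5")]))
  expect_true(any(cm$assumed[cm$trait == "emergence_rate"]))
  expect_true(any(cm$assumed[cm$trait == "coleoptile_weight"]))
})

test_that("interpolated dose curves are unimodal with the peak at the anchor", {
  for (g in c("ly119-2", "ZRX87-1")) {
    cm <- deepseed_preset()$cell_means
    for (tr in c("mesocotyl_length", "iaa_mesocotyl", "coleoptile_weight")) {
      x <- cm[cm$genotype == g & cm$trait == tr &
                cm$treatment %in% dose_treatments(), ]
      x <- x[order(treatment_dose(x$treatment)), ]
      anchor <- which(!x$interpolated)
      expect_length(anchor, 1)
      expect_equal(which.max(x$mean), anchor)
      # single local maximum: increases up to the anchor, decreases after
      expect_true(all(diff(x$mean[seq_len(anchor)]) > 0))
      if (anchor < nrow(x)) {
        expect_true(all(diff(x$mean[anchor:nrow(x)]) < 0))
      }
    }
  }
})

test_that("replicate noise obeys the law of large numbers at the cell level", {
  cm <- deepseed_preset()$cell_means
  cm <- cm[cm$genotype == "ly119-2" & cm$trait != "emergence_rate", ]
  cfg <- generator_config(cell_means = cm, replicates = 400, cv_percent = 10)
  tab <- generate_trait_table(cfg, seed = 9)
  m <- aggregate_means(tab)
  m <- m[!m$trait %in% c("total_length", "mc_ratio"), ]
  key <- paste(m$genotype, m$treatment, m$trait)
  spec <- setNames(cm$mean, paste(cm$genotype, cm$treatment, cm$trait))
  se <- m$sd / sqrt(m$n)
  z <- abs(m$mean - spec[key]) / se
  expect_gte(mean(z < 3), 0.99)
})

test_that("emergence is a binomial proportion over 30 seeds per device", {
  cfg <- deepseed_preset(cv_percent = 10, replicates = 2000)
  cm <- cfg$cell_means
  cfg$cell_means <- cm[cm$trait == "emergence_rate" & cm$genotype == "ly119-2", ]
  tab <- generate_trait_table(cfg, seed = 13)
  v <- tab$value[tab$treatment == "T4"]
  # support is multiples of 100/30
  expect_true(all(abs(v * 30 / 100 - round(v * 30 / 100)) < 1e-9))
  expect_equal(mean(v), 95, tolerance = 0.02)
  expect_equal(sd(v) / 100, sqrt(0.95 * 0.05 / 30), tolerance = 0.1)
  # hard zeros and the assumed 100% control are exact
  expect_true(all(tab$value[tab$treatment == "CK-"] == 0))
  expect_true(all(tab$value[tab$treatment == "CK+"] == 100))
})

test_that("generator config validation catches bad inputs", {
  cm <- data.frame(genotype = "g", treatment = "CK+", trait = "tr_a", mean = 1)
  expect_error(generator_config(cm[, 1:3]), class = "mitieval_config_error")
  expect_error(generator_config(cm, replicates = 0),
               class = "mitieval_config_error")
  expect_error(generator_config(cm, cv_percent = -1),
               class = "mitieval_config_error")
  bad <- data.frame(genotype = "g", treatment = "CK+",
                    trait = "emergence_rate", mean = 150)
  expect_error(generate_trait_table(generator_config(bad), seed = 1),
               class = "mitieval_config_error")
  expect_error(generate_trait_table(list(), seed = 1),
               class = "mitieval_config_error")
})
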