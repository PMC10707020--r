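# Synthetic-data generator for the two-genotype deep-seeding serotonin
# dose-response design: 2 genotypes x 7 treatments x 17 traits x n replicates,
# stress depression at 20 cm, unimodal dose response, replicate noise.

# Quadratic log-ratio dose-response through (dose 0, log-ratio 0) with its
# peak at the anchored dose: log r(c) = log(R) * (1 - ((c - c*) / c*)^2).
# Anchored cells keep the printed ratio exactly; all others are interpolated.
interp_dose_curve <- function(anchor_dose, anchor_ratio,
                              doses = treatment_registry()$dose_mg_per_L[3:7]) {
  f <- 1 - ((doses - anchor_dose) / anchor_dose)^2
  r <- exp(log(anchor_ratio) * f)
  r[doses == anchor_dose] <- anchor_ratio
  list(ratio = r, interpolated = doses != anchor_dose)
}

# per-genotype calibration tables; ratios are Tn/CK- (printed where known),
# stress_ratio is CK-/CK+. Emergence is absolute percent (CK+ assumed 100).
preset_genotype_spec <- function(genotype) {
  if (genotype == "ly119-2") {
    list(
      emergence = c(ck_plus = 100, ck_minus = 0,
                    T1 = 0, T2 = 5, T3 = 60, T4 = 95, T5 = 30),
      full = list(
        seedling_weight = list(r0 = 1 - 0.577,
                               r = c(1.23, 1.18, 2.11, 2.42, 2.24)),
        seedling_length = list(r0 = 1 - 0.509,
                               r = c(1.62, 1.28, 2.21, 2.70, 2.47)),
        h2o2_mesocotyl = list(r0 = 2.81,
                              r = 1 - c(0.1249, 0.1387, 0.3220, 0.6749, 0.0633)),
        h2o2_coleoptile = list(r0 = 1.83,
                               r = 1 - c(0.1228, 0.2032, 0.4810, 0.3713, 0.2544)),
        lignin_mesocotyl = list(r0 = 1 - 0.2178,
                                r = 1 - c(0.1648, 0.1307, 0.3295, 0.5682, 0.0455)),
        lignin_coleoptile = list(r0 = 1 - 0.2584,
                                 r = 1 - c(0.1910, 0.2613, 0.2462, 0.4623, 0.2010))
      ),
      anchored = list(
        mesocotyl_length  = list(r0 = 4.92,  dose = 2.5, ratio = 1.891),
        coleoptile_length = list(r0 = 1.48,  dose = 2.5, ratio = 1.774),
        mesocotyl_coarse  = list(r0 = 1 - 0.561, dose = 2.0, ratio = 1 + 2.809),
        coleoptile_coarse = list(r0 = 1 - 0.156, dose = 3.0, ratio = 1 + 1.664),
        mesocotyl_weight  = list(r0 = 1 + 0.713, dose = 2.5, ratio = 1.473),
        coleoptile_weight = list(r0 = 0.95, dose = 3.0, ratio = 1 + 1.199,
                                 assumed_r0 = TRUE),
        iaa_mesocotyl     = list(r0 = 2.81, dose = 2.5, ratio = 2.64),
        iaa_coleoptile    = list(r0 = 1.55, dose = 2.5, ratio = 1.38)
      ),
      # coleoptile/mesocotyl baseline solved from the printed CK- total-length
      # ratio: 4.92 m + 1.48 k = 2.80 (m + k)
      coleoptile_baseline = (4.92 - 2.80) / (2.80 - 1.48)
    )
  } else if (genotype == "ZRX87-1") {
    list(
      emergence = c(ck_plus = 100, ck_minus = 0,
                    T1 = 0, T2 = 0, T3 = 15, T4 = 50, T5 = 0),
      full = list(
        seedling_weight = list(r0 = 1 - 0.258,
                               r = c(1.11, 1.26, 2.02, 2.03, 0.93)),
        seedling_length = list(r0 = 1 - 0.270,
                               r = c(1.19, 1.31, 1.73, 1.86, 1.19)),
        h2o2_mesocotyl = list(r0 = 4.21,
                              r = 1 - c(0.1722, 0.2879, 0.4051, 0.6114, 0.0764)),
        h2o2_coleoptile = list(r0 = 2.16,
                               r = 1 - c(0.0372, 0.1787, 0.4822, 0.5542, 0.0323)),
        lignin_mesocotyl = list(r0 = 1 - 0.3277,
                                r = 1 - c(0.0985, 0.0303, 0.2576, 0.4924, 0.1439)),
        lignin_coleoptile = list(r0 = 1 - 0.0415,
                                 r = 1 - c(0.0649, 0.1297, 0.4919, 0.5730, 0.0703))
      ),
      anchored = list(
        mesocotyl_length  = list(r0 = 1.77, dose = 2.5, ratio = 1.344),
        coleoptile_length = list(r0 = 1.05, dose = 2.5, ratio = 1.868),
        mesocotyl_coarse  = list(r0 = 1 - 0.312, dose = 1.0, ratio = 1.097),
        coleoptile_coarse = list(r0 = 1 - 0.257, dose = 1.5, ratio = 1.364),
        mesocotyl_weight  = list(r0 = 1 - 0.109, dose = 2.5, ratio = 1.897),
        coleoptile_weight = list(r0 = 0.95, dose = 2.5, ratio = 1.465,
                                 assumed_r0 = TRUE),
        iaa_mesocotyl     = list(r0 = 1.15, dose = 2.5, ratio = 1.36),
        iaa_coleoptile    = list(r0 = 1.11, dose = 2.5, ratio = 1.30)
      ),
      coleoptile_baseline = (1.77 - 1.40) / (1.40 - 1.05)
    )
  } else {
    abort("mitieval_config_error", sprintf("no preset for genotype %s",
                                           genotype))
  }
}

# expand a genotype spec into a long cell-mean table
preset_cell_means <- function(genotype) {
  sp <- preset_genotype_spec(genotype)
  trts <- treatment_registry()
  tns <- dose_treatments()
  rows <- list()
  add <- function(trait, values, interpolated, assumed = FALSE) {
    rows[[trait]] <<- data.frame(
      genotype = genotype, treatment = trts$code, trait = trait,
      mean = values, interpolated = interpolated,
      assumed = assumed, derived = FALSE, stringsAsFactors = FALSE
    )
  }
  em <- sp$emergence
  add("emergence_rate",
      c(em[["ck_plus"]], em[["ck_minus"]], em[tns]),
      interpolated = rep(FALSE, 7),
      assumed = c(TRUE, rep(FALSE, 6)))  # CK+ emergence never printed
  for (tr in names(sp$full)) {
    s <- sp$full[[tr]]
    ckm <- s$r0
    add(tr, c(1, ckm, ckm * s$r), interpolated = rep(FALSE, 7))
  }
  for (tr in names(sp$anchored)) {
    s <- sp$anchored[[tr]]
    base <- if (tr == "coleoptile_length") sp$coleoptile_baseline else 1
    cur <- interp_dose_curve(s$dose, s$ratio)
    ckm <- base * s$r0
    add(tr, c(base, ckm, ckm * cur$ratio),
        interpolated = c(FALSE, FALSE, cur$interpolated),
        assumed = isTRUE(s$assumed_r0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrated generator preset for the deep-seeding serotonin experiment
#'
#' Builds a [generator_config()] whose cell-mean structure reproduces, in
#' normalized units, the published fold-changes and percent changes of the
#' two-genotype (ly119-2, ZRX87-1) deep-seeding serotonin dose-response
#' study: stress depression of growth traits at 20 cm, elevated IAA and
#' H2O2 and reduced lignin under stress, and a unimodal 5-HT dose response
#' whose printed optimum is 2.5 mg/L for most traits. Cells never printed
#' are filled by a quadratic interpolation on the log-ratio scale peaking at
#' the anchored (printed-best) dose and are tagged `interpolated`; assumed
#' values (unstressed-control emergence = 100%, a small non-significant
#' coleoptile-weight change under stress) are tagged `assumed`.
#'
#' Total length and the mesocotyl-to-coleoptile ratio are derived per
#' replicate from the generated mesocotyl and coleoptile lengths, never
#' drawn independently; coleoptile baselines are solved so the derived
#' stressed-control ratios match the printed ones.
#'
#' @param cv_percent replicate coefficient of variation in percent (default
#'   10); 0 gives noise-free replicates equal to the cell means.
#' @param replicates replicates per cell (default 5).
#' @return A `generator_config` object.
#' @export
deepseed_preset <- function(cv_percent = 10, replicates = 5) {
  cells <- rbind(preset_cell_means("ly119-2"), preset_cell_means("ZRX87-1"))
  generator_config(
    cell_means = cells,
    replicates = replicates,
    cv_percent = cv_percent,
    distribution = "normal-truncated-at-0",
    ct_block = preset_ct_block()
  )
}

#' Construct a generator configuration
#'
#' @param cell_means data frame `genotype`, `treatment`, `trait`, `mean`
#'   (plus optional logical `interpolated`, `assumed`, `derived` tags). The
#'   trait `emergence_rate`, if present, is generated as a binomial
#'   proportion (30 seeds per device) on the percent scale; `total_length`
#'   and `mc_ratio` need not be listed — they are derived per replicate from
#'   `mesocotyl_length` and `coleoptile_length` when those are present.
#' @param replicates replicates per cell (>= 1).
#' @param cv_percent replicate CV in percent (>= 0).
#' @param distribution `"normal-truncated-at-0"` (default) or `"lognormal"`
#'   for non-proportion traits.
#' @param ct_block optional Ct-generator block, see [preset_ct_block()].
#' @param binomial_trials seeds per emergence device (default 30).
#' @return A `generator_config` object.
#' @export
generator_config <- function(cell_means, replicates = 5, cv_percent = 10,
                             distribution = c("normal-truncated-at-0",
                                              "lognormal"),
                             ct_block = NULL, binomial_trials = 30) {
  distribution <- match.arg(distribution)
  need <- c("genotype", "treatment", "trait", "mean")
  miss <- setdiff(need, names(cell_means))
  if (length(miss)) {
    abort("mitieval_config_error",
          sprintf("cell_means lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (replicates < 1) abort("mitieval_config_error", "replicates must be >= 1")
  if (cv_percent < 0) abort("mitieval_config_error", "cv_percent must be >= 0")
  for (tag in c("interpolated", "assumed")) {
    if (is.null(cell_means[[tag]])) cell_means[[tag]] <- FALSE
  }
  structure(
    list(cell_means = cell_means, replicates = replicates,
         cv_percent = cv_percent, distribution = distribution,
         ct_block = ct_block, binomial_trials = binomial_trials),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cm <- x$cell_means
  cat(sprintf(paste0("Generator config: %d genotype(s), %d treatment(s), ",
                     "%d trait(s); %d replicates, CV %.1f%% (%s)\n"),
              length(unique(cm$genotype)), length(unique(cm$treatment)),
              length(unique(cm$trait)), x$replicates, x$cv_percent,
              x$distribution))
  cat(sprintf("  interpolated cells: %d, assumed cells: %d\n",
              sum(cm$interpolated), sum(cm$assumed)))
  if (!is.null(x$ct_block)) {
    cat(sprintf("  Ct block: %d target gene(s) + reference %s\n",
                nrow(x$ct_block$genes), x$ct_block$reference_gene))
  }
  invisible(x)
}

# positive truncated normal by rejection; cv = 0 degenerates to the mean
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Generate a replicate-level trait table from a generator configuration
#'
#' Draws `replicates` values per (genotype, treatment, trait) cell:
#' truncated-normal (or lognormal) noise with standard deviation
#' `cv_percent/100 * mean` for continuous traits, and a binomial count over
#' 30 seeds per device, rescaled to percent, for the emergence rate. With
#' `cv_percent = 0` every replicate equals its cell mean exactly (the
#' emergence rate included). Total length and the mesocotyl-to-coleoptile
#' ratio are computed per replicate from the generated mesocotyl and
#' coleoptile lengths, so the additive and ratio identities hold exactly in
#' every replicate. Cells are generated in a fixed order, so a fixed seed
#' gives an identical table.
#'
#' @param config a `generator_config`, e.g. [deepseed_preset()].
#' @param seed integer seed for reproducibility (`NULL` to use the current
#'   RNG state).
#' @return A `trait_table` data frame.
#' @export
generate_trait_table <- function(config, seed = NULL) {
  if (!inherits(config, "generator_config")) {
    abort("mitieval_config_error", "config must be a generator_config")
  }
  if (!is.null(seed)) set.seed(seed)
  cm <- config$cell_means
  cm <- cm[order(cm$genotype, cm$treatment, cm$trait), , drop = FALSE]
  nrep <- config$replicates
  cv <- config$cv_percent / 100
  rows <- vector("list", nrow(cm))
  for (i in seq_len(nrow(cm))) {
    mu <- cm$mean[i]
    tr <- cm$trait[i]
    v <- if (tr == "emergence_rate") {
      if (cv == 0) {
        rep(mu, nrep)
      } else {
        p <- mu / 100
        if (p < 0 || p > 1) {
          abort("mitieval_config_error",
                sprintf("emergence mean %.3g%% outside [0, 100]", mu))
        }
        100 * stats::rbinom(nrep, config$binomial_trials, p) /
          config$binomial_trials
      }
    } else if (config$distribution == "lognormal") {
      if (mu <= 0) {
        abort("mitieval_config_error",
              sprintf("lognormal needs positive mean (trait %s)", tr))
      }
      if (cv == 0) rep(mu, nrep) else {
        s2 <- log(1 + cv^2)
        stats::rlnorm(nrep, log(mu) - s2 / 2, sqrt(s2))
      }
    } else {
      rtruncnorm_pos(nrep, mu, cv * mu)
    }
    rows[[i]] <- data.frame(
      genotype = cm$genotype[i], treatment = cm$treatment[i],
      replicate = seq_len(nrep), trait = tr, value = v,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  # derived traits from components, never drawn
  comp <- c("mesocotyl_length", "coleoptile_length")
  if (all(comp %in% cm$trait) && !"total_length" %in% cm$trait) {
    ml <- out[out$trait == "mesocotyl_length", ]
    cl <- out[out$trait == "coleoptile_length", ]
    stopifnot(all(ml$genotype == cl$genotype),
              all(ml$treatment == cl$treatment),
              all(ml$replicate == cl$replicate))
    tot <- ml; tot$trait <- "total_length"; tot$value <- ml$value + cl$value
    rat <- ml; rat$trait <- "mc_ratio";     rat$value <- ml$value / cl$value
    out <- rbind(out, tot, rat)
  }
  out <- out[order(out$genotype, out$treatment, out$trait, out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Default Ct-generator block
#'
#' Eight target genes (four IAA biosynthesis/signalling, four lignin
#' biosynthesis) plus the Actin 1 reference, measured in the mesocotyl and
#' coleoptile under the unstressed control, stressed control and the 2.5
#' mg/L dose (T4). IAA-pathway targets are up-regulated under stress and
#' further under T4 (Ct shifted down); lignin-pathway targets the reverse.
#' Effects are in cycles: `stress_effect` for CK- vs CK+, plus
#' `dose_effect` more for T4.
#'
#' @param stress_effect cycles shifted under CK- (default 1.5).
#' @param dose_effect additional cycles under T4 (default 1.0).
#' @param noise_sd replicate Gaussian Ct noise, cycles (default 0.3).
#' @param replicates qPCR replicates per cell (default 3).
#' @return List describing the Ct block.
#' @export
preset_ct_block <- function(stress_effect = 1.5, dose_effect = 1.0,
                            noise_sd = 0.3, replicates = 3) {
  genes <- data.frame(
    gene = c("Zm00001d049601", "Zm00001d039346", "Zm00001d026530",
             "Zm00001d049659", "Zm00001d016471", "Zm00001d005998",
             "Zm00001d032152", "Zm00001d053554"),
    pathway = rep(c("iaa", "lignin"), each = 4),
    direction = rep(c("up", "down"), each = 4),
    baseline_ct = 26,
    stringsAsFactors = FALSE
  )
  list(genes = genes, reference_gene = "Zm00001d010159", reference_ct = 20,
       stress_effect = stress_effect, dose_effect = dose_effect,
       noise_sd = noise_sd, replicates = replicates,
       genotypes = c("ly119-2", "ZRX87-1"),
       treatments = c("CK+", "CK-", "T4"),
       tissues = c("mesocotyl", "coleoptile"))
}

#' Generate a qPCR Ct table from a generator configuration
#'
#' The reference gene's Ct is stable across cells (noise only); each target
#' gene's Ct is shifted from its baseline by the configured stress and dose
#' effects, downwards for up-regulated (IAA-pathway) genes and upwards for
#' down-regulated (lignin-pathway) genes, with Gaussian replicate noise in
#' cycles.
#'
#' @param config a `generator_config` whose `ct_block` is set
#'   (e.g. [deepseed_preset()]), or a Ct block from [preset_ct_block()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return A `ct_table` data frame.
#' @export
generate_ct_table <- function(config, seed = NULL) {
  blk <- if (inherits(config, "generator_config")) config$ct_block else config
  if (is.null(blk)) {
    abort("mitieval_config_error", "config has no ct_block")
  }
  if (!is.null(seed)) set.seed(seed)
  shift_for <- function(treatment, direction) {
    eff <- switch(treatment,
                  "CK+" = 0,
                  "CK-" = blk$stress_effect,
                  blk$stress_effect + blk$dose_effect)
    if (direction == "up") -eff else eff
  }
  rows <- list()
  k <- 0L
  for (g in blk$genotypes) for (trt in blk$treatments)
    for (ti in blk$tissues) {
      for (j in seq_len(nrow(blk$genes))) {
        gn <- blk$genes[j, ]
        mu <- gn$baseline_ct + shift_for(trt, gn$direction)
        k <- k + 1L
        rows[[k]] <- data.frame(
          genotype = g, treatment = trt, tissue = ti, gene = gn$gene,
          replicate = seq_len(blk$replicates),
          ct = mu + stats::rnorm(blk$replicates, 0, blk$noise_sd),
          stringsAsFactors = FALSE
        )
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        genotype = g, treatment = trt, tissue = ti,
        gene = blk$reference_gene, replicate = seq_len(blk$replicates),
        ct = blk$reference_ct + stats::rnorm(blk$replicates, 0, blk$noise_sd),
        stringsAsFactors = FALSE
      )
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  out
}
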