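#' Treatment registry for the deep-seeding dose-response design
#'
#' The design crosses two sowing depths with exogenous serotonin (5-HT)
#' doses: `CK+` is the unstressed control (3 cm depth, no 5-HT), `CK-` the
#' stressed control (20 cm depth, no 5-HT), and `T1`--`T5` are the 20 cm
#' depth with 1.0, 1.5, 2.0, 2.5 and 3.0 mg/L 5-HT respectively.
#'
#' @return A data frame with columns `code`, `depth_cm`, `dose_mg_per_L`.
#' @examples
#' treatment_registry()
#' @export
treatment_registry <- function() {
  data.frame(
    code = c("CK+", "CK-", "T1", "T2", "T3", "T4", "T5"),
    depth_cm = c(3, rep(20, 6)),
    dose_mg_per_L = c(0, 0, 1.0, 1.5, 2.0, 2.5, 3.0),
    stringsAsFactors = FALSE
  )
}

treatment_codes <- function() treatment_registry()$code
dose_treatments <- function() c("T1", "T2", "T3", "T4", "T5")

#' Look up the 5-HT dose of a treatment code
#'
#' @param code character vector of treatment codes.
#' @return Numeric vector of doses in mg/L.
#' @export
treatment_dose <- function(code) {
  reg <- treatment_registry()
  idx <- match(code, reg$code)
  if (anyNA(idx)) {
    abort("mitieval_schema_error",
          sprintf("unknown treatment code(s): %s",
                  paste(unique(code[is.na(idx)]), collapse = ", ")))
  }
  reg$dose_mg_per_L[idx]
}

#' Default registry of the 17 seedling traits
#'
#' Each trait carries its tolerance direction: `"positive"` if larger values
#' indicate stronger deep-seeding tolerance (so mitigation should raise the
#' trait back towards/beyond the unstressed control), `"negative"` if smaller
#' values do (H2O2, lignin, and the mesocotyl-to-coleoptile ratio). The
#' direction selects which form of the mitigation effect index is applied.
#' Only the seedling emergence rate is a proportion (percent scale, 0--100).
#'
#' The default directions reflect the observed physiology: mitigation of
#' deep-seeding stress raises emergence, biomass, elongation and IAA, and
#' lowers H2O2, lignin and the mesocotyl-to-coleoptile ratio. They can be
#' overridden per trait (see [read_direction_override()]).
#'
#' @return A data frame with columns `trait`, `direction`, `units`,
#'   `is_proportion`.
#' @export
trait_registry <- function() {
  pos <- c(
    emergence_rate    = "%",
    seedling_length   = "cm",
    seedling_weight   = "g",
    mesocotyl_length  = "cm",
    coleoptile_length = "cm",
    mesocotyl_coarse  = "mm",
    coleoptile_coarse = "mm",
    mesocotyl_weight  = "g",
    coleoptile_weight = "g",
    total_length      = "cm",
    iaa_mesocotyl     = "ng g-1 FW",
    iaa_coleoptile    = "ng g-1 FW"
  )
  neg <- c(
    mc_ratio          = "dimensionless",
    h2o2_mesocotyl    = "uM g-1 FW",
    h2o2_coleoptile   = "uM g-1 FW",
    lignin_mesocotyl  = "A280 g-1",
    lignin_coleoptile = "A280 g-1"
  )
  data.frame(
    trait = c(names(pos), names(neg)),
    direction = c(rep("positive", length(pos)), rep("negative", length(neg))),
    units = c(unname(pos), unname(neg)),
    is_proportion = c(names(pos), names(neg)) == "emergence_rate",
    stringsAsFactors = FALSE
  )
}

#' Extract a named direction vector from a trait registry
#'
#' @param registry a trait registry data frame as from [trait_registry()].
#' @return Named character vector mapping trait to `"positive"`/`"negative"`.
#' @export
trait_directions <- function(registry = trait_registry()) {
  stats::setNames(registry$direction, registry$trait)
}

#' Override trait tolerance directions from a YAML or JSON file
#'
#' The file must contain a flat mapping from trait name to `"positive"` or
#' `"negative"`, e.g. `mc_ratio: positive`. Unlisted traits keep their
#' default direction; unknown trait names are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param directions base direction vector to override
#'   (default [trait_directions()]).
#' @return Named character vector of directions.
#' @export
read_direction_override <- function(path, directions = trait_directions()) {
  if (!file.exists(path)) {
    abort("mitieval_io_error", sprintf("file not found: %s", path))
  }
  ov <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ov <- unlist(ov)
  bad <- setdiff(names(ov), names(directions))
  if (length(bad)) {
    abort("mitieval_registry_error",
          sprintf("direction override names unknown trait(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!all(ov %in% c("positive", "negative"))) {
    abort("mitieval_registry_error",
          "directions must be 'positive' or 'negative'")
  }
  directions[names(ov)] <- unname(ov)
  directions
}
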