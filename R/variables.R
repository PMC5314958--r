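#' Canonical gradient variables and their motivation groups
#'
#' The analysis distinguishes fifteen independent variables in three groups:
#' six biophysical variables whose even coverage defines *representativeness*
#' (climate, relief, soil), five variables tied to *preferential* motivations
#' (tourism attractiveness, proximity to international frontiers, standing
#' biomass, and animal / vascular-plant species richness — the last two
#' jointly depicting the single "biological conservation" motivation), and
#' four variables tied to *opportunistic* forces (population, isolation from
#' cities, distance to coasts, cropland suitability).
#'
#' The `motivation` column records which variables share a motivation:
#' `animal_richness` and `plant_richness` both carry
#' `"biological_conservation"`, which is why [group_averages()] pre-averages
#' them before averaging a group.
#'
#' @return A data frame with columns `variable`, `group` (one of
#'   `"representative"`, `"preferential"`, `"opportunistic"`), and
#'   `motivation`.
#' @examples
#' variable_table()
#' @export
variable_table <- function() {
  data.frame(
    variable = c(
      "temperature", "precipitation", "ppt_pet", "elevation", "slope",
      "soil_fertility",
      "tourism", "frontiers", "biomass", "animal_richness", "plant_richness",
      "population", "isolation", "coasts", "cropland_suitability"
    ),
    group = c(
      rep("representative", 6L),
      rep("preferential", 5L),
      rep("opportunistic", 4L)
    ),
    motivation = c(
      rep("representativeness", 6L),
      "tourism_leisure", "frontier_protection", "goods_and_services",
      "biological_conservation", "biological_conservation",
      rep("opportunity", 4L)
    ),
    stringsAsFactors = FALSE
  )
}

variable_names <- function(group = NULL) {
  vt <- variable_table()
  if (is.null(group)) vt$variable else vt$variable[vt$group %in% group]
}

#' Forest predictors: preferential + opportunistic variables
#'
#' Biophysical variables are excluded from the random forest on purpose —
#' their importance would measure representativeness itself, not a
#' preference or an opportunity acting along it.
#'
#' @return Character vector of the nine predictor names.
#' @export
forest_predictors <- function() {
  variable_names(c("preferential", "opportunistic"))
}
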