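# Dietary supply: convert predicted grain concentrations into the percent
# of the estimated average requirement (EAR) met by a reference per-capita
# intake of the crop, with quartile display classes.

#' Default intake and EAR reference table
#'
#' Reference per-capita staple intakes (FAO food-balance figures: wheat
#' 97.6 g/day and teff 89.3 g/day for Ethiopia, maize 342.8 g/day for
#' Malawi) and EAR thresholds for an adult woman aged 18-24 years on an
#' unrefined (high-phytate) diet: Ca 860 mg/day, Fe 22.4 mg/day,
#' Se 45 ug/day, Zn 10.2 mg/day.
#'
#' Note on Se units: grain Se is measured in ug/kg (not mg/kg as for the
#' other elements), so its EAR is carried in ug/day; [percent_ear()]
#' refuses mixed-unit combinations rather than silently converting.
#'
#' @return A list with tibbles `intakes` (`crop`, `intake_g_day`) and
#'   `ears` (`element`, `ear`, `ear_unit`, `conc_unit`).
#' @export
intake_ear_defaults <- function() {
  list(
    intakes = tibble::tibble(
      crop = c("wheat", "teff", "maize"),
      intake_g_day = c(97.6, 89.3, 342.8)),
    ears = tibble::tibble(
      element = c("Ca", "Fe", "Se", "Zn"),
      ear = c(860, 22.4, 45, 10.2),
      ear_unit = c("mg_day", "mg_day", "ug_day", "mg_day"),
      conc_unit = c("mg_kg", "mg_kg", "ug_kg", "mg_kg")))
}

#' Percent of the EAR met by a staple intake
#'
#' `100 * concentration * (intake_g_day / 1000) / ear`: the percentage of
#' the daily requirement delivered by consuming `intake_g_day` grams of
#' grain at the given concentration. Linear in both concentration and
#' intake; values above 100 are not capped.
#'
#' @param concentration Grain concentration, mg/kg (ug/kg for Se), > 0.
#' @param intake_g_day Grain intake, g per capita per day, > 0.
#' @param ear Estimated average requirement per day, in the unit matching
#'   the concentration (mg/day with mg/kg; ug/day with ug/kg).
#' @param conc_unit,ear_unit Unit tags, checked for consistency
#'   (`"mg_kg"`/`"mg_day"` or `"ug_kg"`/`"ug_day"`).
#' @param element Optional element name used in the unit-mismatch error.
#' @return Percent of requirement (same length as `concentration`).
#' @examples
#' percent_ear(64.5, 342.8, 860)   # maize-median Ca: ~2.6% of the Ca EAR
#' @export
percent_ear <- function(concentration, intake_g_day, ear,
                        conc_unit = "mg_kg", ear_unit = "mg_day",
                        element = NULL) {
  if (sub("_.*", "", conc_unit) != sub("_.*", "", ear_unit)) {
    abort(paste0("Unit mismatch", if (!is.null(element)) paste0(" for ", element),
                 ": concentration in ", conc_unit, " against EAR in ",
                 ear_unit, "."))
  }
  if (any(concentration <= 0) || intake_g_day <= 0 || ear <= 0) {
    abort("concentration, intake_g_day and ear must all be positive.")
  }
  100 * concentration * (intake_g_day / 1000) / ear
}

#' Concentration delivering a given percent of the EAR
#'
#' Inverse of [percent_ear()]: the grain concentration at which
#' `intake_g_day` grams per day deliver `percent` percent of the EAR.
#'
#' @inheritParams percent_ear
#' @param percent Percent of requirement.
#' @return Concentration in the EAR-consistent unit.
#' @export
ear_concentration <- function(percent, intake_g_day, ear) {
  percent / 100 * ear / (intake_g_day / 1000)
}

#' Percent-of-EAR surface from a kriged concentration map
#'
#' Applies [percent_ear()] nodewise to the `prediction` column of a
#' [krige_grid()] result for a given crop and element, carrying any
#' `masked` column through, and attaches quartile display classes computed
#' from the unmasked nodes.
#'
#' @param grid A [krige_grid()] tibble (back-transformed concentrations).
#' @param crop,element Crop and element names looked up in `table`.
#' @param table Reference table, default [intake_ear_defaults()].
#' @return `grid` with `percent` and `class` columns added.
#' @export
percent_ear_grid <- function(grid, crop, element,
                             table = intake_ear_defaults()) {
  ik <- match(crop, table$intakes$crop)
  ek <- match(element, table$ears$element)
  if (is.na(ik)) abort(paste0("Unknown crop: ", crop))
  if (is.na(ek)) abort(paste0("Unknown element: ", element))
  er <- table$ears[ek, ]
  grid$percent <- percent_ear(grid$prediction,
                              table$intakes$intake_g_day[ik], er$ear,
                              conc_unit = er$conc_unit, ear_unit = er$ear_unit,
                              element = element)
  mask <- if ("masked" %in% names(grid)) grid$masked else NULL
  grid$class <- quartile_classes(grid$percent, mask)
  grid
}

#' Quartile display classes
#'
#' Class breaks at the 25th/50th/75th percentiles (type 7) of the unmasked
#' values; masked nodes are excluded both from break computation and from
#' classing (class `NA`). Classes are monotone in the value.
#'
#' @param values Numeric vector (e.g. percent-of-EAR per node).
#' @param mask Optional logical vector; `TRUE` nodes are excluded.
#' @return Integer classes 1-4 (`NA` where masked).
#' @export
quartile_classes <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  use <- !mask & is.finite(values)
  if (sum(use) < 4) abort("Need at least 4 unmasked values for quartile classes.")
  v <- values[use]
  if (max(v) == min(v)) {
    warn("All unmasked values identical: a single class is returned.")
    cls <- rep(NA_integer_, length(values))
    cls[use] <- 1L
    return(cls)
  }
  breaks <- quantile(v, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  cls <- rep(NA_integer_, length(values))
  cls[use] <- findInterval(values[use], breaks) + 1L
  cls
}
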