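#' Occupational exposure scenario
#'
#' Bundles the dosimetric quantities needed to convert a physical dose rate
#' into the model's dose-rate parameter `lambda` (expected successful hits
#' per cell per cell-cycle length):
#' * `dose_rate` - dose rate during exposure, mGy per hour.
#' * `exposed_hours_per_cycle` - hours of exposure accrued per cell-cycle
#'   length (e.g. 8 working hours when the cell cycle is 24 h).
#' * `elemental_dose` - the lowest dose a single radiation track delivers to
#'   a cell nucleus, mGy per hit; about 1 mGy for gamma rays in a typical
#'   mammalian nucleus.
#' * `hit_to_damage_prob` - probability `H` in `[0, 1]` that a hit converts
#'   an intact cell (repair is folded into `H`).
#'
#' @param dose_rate mGy/h, `>= 0`.
#' @param exposed_hours_per_cycle hours per cell cycle, `>= 0`.
#' @param elemental_dose mGy per hit, `> 0`.
#' @param hit_to_damage_prob probability in `[0, 1]`.
#' @return A list of class `occupational_scenario`.
#' @export
occupational_scenario <- function(dose_rate, exposed_hours_per_cycle,
                                  elemental_dose = 1,
                                  hit_to_damage_prob = 1) {
  stopifnot(dose_rate >= 0, exposed_hours_per_cycle >= 0,
            hit_to_damage_prob >= 0, hit_to_damage_prob <= 1)
  if (!is.finite(elemental_dose) || elemental_dose <= 0) {
    stop("elemental_dose must be > 0 mGy", call. = FALSE)
  }
  structure(
    list(dose_rate = dose_rate,
         exposed_hours_per_cycle = exposed_hours_per_cycle,
         elemental_dose = elemental_dose,
         hit_to_damage_prob = hit_to_damage_prob),
    class = "occupational_scenario"
  )
}

#' Convert an exposure scenario to the dose-rate parameter lambda
#'
#' `lambda = dose_rate * exposed_hours_per_cycle * H / elemental_dose`:
#' dose accrued per cell cycle, divided by the dose per track hit, times the
#' probability a hit damages the cell. For a radiation worker at the
#' 20 mGy/year occupational limit (0.01 mGy/h over 8-h workdays), a 24-h
#' cell cycle and `H = 1`, this gives `lambda = 0.08` hits per cell per
#' cycle - one hit per cell every 12.5 working days.
#'
#' @param sc an [occupational_scenario()].
#' @return `lambda`, expected successful hits per cell per cell cycle.
#' @examples
#' occupational_lambda(occupational_scenario(0.01, 8)) # 0.08
#' @export
occupational_lambda <- function(sc) {
  stopifnot(inherits(sc, "occupational_scenario"))
  sc$dose_rate * sc$exposed_hours_per_cycle * sc$hit_to_damage_prob /
    sc$elemental_dose
}

#' Dose rate implied by an annual dose spread over working hours
#'
#' E.g. 20 mGy/year over 250 working days of 8 h gives 0.01 mGy/h.
#'
#' @param annual_dose mGy per year.
#' @param working_days days per year over which the dose accrues.
#' @param hours_per_day exposed hours per working day.
#' @return Dose rate in mGy/h.
#' @export
occupational_dose_rate <- function(annual_dose, working_days, hours_per_day) {
  stopifnot(annual_dose >= 0, working_days > 0, hours_per_day > 0)
  annual_dose / (working_days * hours_per_day)
}

#' Working days needed to accumulate one elemental dose
#'
#' At 0.01 mGy/h and 8-h workdays, one 1-mGy elemental dose takes 100 h of
#' exposure, i.e. 12.5 working days.
#'
#' @param dose_rate mGy/h, `> 0`.
#' @param hours_per_day exposed hours per working day, `> 0`.
#' @param elemental_dose mGy per hit, `> 0`.
#' @return Number of working days.
#' @export
working_days_per_hit <- function(dose_rate, hours_per_day,
                                 elemental_dose = 1) {
  stopifnot(dose_rate > 0, hours_per_day > 0, elemental_dose > 0)
  elemental_dose / (dose_rate * hours_per_day)
}
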