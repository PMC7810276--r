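#' Estimate total body water from sex and weight
#'
#' Standard adult fixed-fraction estimate: TBW = 0.6 x weight for men and
#' 0.5 x weight for women, rounded to whole litres to match how TBW is
#' charted clinically. A chart-supplied TBW should always take precedence
#' over this estimate; the bundled validation cohort carries its own TBW
#' values and never goes through this function. No height-based (Watson)
#' formula is offered because it could not be validated against the
#' bundled cohort, which reports no heights.
#'
#' @param sex `"male"`/`"M"` or `"female"`/`"F"` (vectorized, recycled
#'   against `weight`).
#' @param weight body weight in kg; positive.
#' @param fraction_override optional TBW fraction in (0, 1) replacing the
#'   sex-based default (e.g. 0.5 for elderly or lean men).
#' @return Estimated TBW in whole litres.
#' @examples
#' estimate_tbw("male", 100)  # 60
#' estimate_tbw("female", 50) # 25
#' @export
estimate_tbw <- function(sex, weight, fraction_override = NULL) {
  check_positive(weight, "weight")
  sx <- normalize_sex(sex)
  if (!is.null(fraction_override)) {
    if (!is_number(fraction_override) ||
        fraction_override <= 0 || fraction_override >= 1) {
      stop_invalid("`fraction_override` must be a single number in (0, 1)")
    }
    fraction <- rep_len(fraction_override, length(weight))
  } else {
    fraction <- ifelse(rep_len(sx, length(weight)) == "male", 0.6, 0.5)
  }
  round(fraction * weight)
}

normalize_sex <- function(sex) {
  sx <- c(m = "male", male = "male", f = "female", female = "female")[
    tolower(as.character(sex))]
  if (any(is.na(sx))) {
    stop_invalid("`sex` must be \"male\"/\"M\" or \"female\"/\"F\"")
  }
  unname(sx)
}
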