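# Core closed-form predictors of the plasma sodium change after one
# crystalloid bolus, evaluated at steady state (the cohort allowed ~6 h
# between measurements for the kidneys to process the load). All arithmetic
# is unrounded; use round_display() for 0.1 mmol/L presentation.

MODEL_NAMES <- c("voets", "adrogue_madias")

#' Patient state for sodium prediction
#'
#' The physiological inputs of the prediction models. Fields may be vectors
#' of equal length, one element per patient/measurement.
#'
#' @param tbw total body water in L (see [estimate_tbw()] when only sex and
#'   weight are known; a measured or chart-supplied TBW always takes
#'   precedence over estimation).
#' @param na_plasma pre-infusion plasma sodium \eqn{[Na^+]_p} in mmol/L.
#' @param urine_osm urine osmolality \eqn{O_u} in mOsmol/L; assumed fixed
#'   over the infusion, the defining SIADH assumption.
#' @return Object of class `"patient_state"`.
#' @export
patient_state <- function(tbw, na_plasma, urine_osm) {
  check_positive(tbw, "tbw")
  check_positive(na_plasma, "na_plasma")
  check_positive(urine_osm, "urine_osm")
  n <- max(length(tbw), length(na_plasma), length(urine_osm))
  structure(
    list(tbw = rep_len(tbw, n),
         na_plasma = rep_len(na_plasma, n),
         urine_osm = rep_len(urine_osm, n)),
    class = "patient_state"
  )
}

#' One crystalloid infusion
#'
#' @param volume infusate volume \eqn{V_i} in L; positive.
#' @param infusate an [infusate()] object or a bare NaCl mass-percent.
#' @return Object of class `"infusion_event"` carrying `volume`, `na_conc`
#'   (\eqn{[Na^+]_i}) and `tonicity` (\eqn{O_i}).
#' @export
infusion_event <- function(volume, infusate) {
  check_positive(volume, "volume")
  inf <- as_infusate(infusate)
  structure(
    list(volume = volume, infusate = inf,
         na_conc = inf$na_conc, tonicity = inf$tonicity),
    class = "infusion_event"
  )
}

# accept objects or plain numerics for the low-level model functions
state_fields <- function(state) {
  if (!inherits(state, "patient_state")) {
    stop_invalid("`state` must be a patient_state()")
  }
  state
}

infusion_fields <- function(infusion) {
  if (!inherits(infusion, "infusion_event")) {
    stop_invalid("`infusion` must be an infusion_event()")
  }
  infusion
}

#' Voets equation: sodium change from the electrolyte-free water balance
#'
#' Predicts the plasma sodium change after a crystalloid bolus in SIADH,
#' accounting for both infusate input and (tonicity-matched) urine output:
#' \deqn{\Delta [Na^+]_p = [Na^+]_p \frac{V_i}{TBW}
#'       \left(f \frac{O_i}{O_u} - 1\right)}
#' with \eqn{f} the osmolality-to-tonicity factor, 1.7 by default. The
#' prediction is positive exactly when \eqn{O_u < f O_i}: saline raises the
#' plasma sodium only while the urine is less concentrated than the
#' critical osmolality [critical_urine_osmolality()]. The result is exactly
#' linear in the infused volume.
#'
#' @param state a [patient_state()].
#' @param infusion an [infusion_event()].
#' @param tonicity_factor dimensionless conversion from urine osmolality to
#'   maximum urine tonicity; the model's single empirical constant,
#'   default 1.7.
#' @return Unrounded predicted \eqn{\Delta [Na^+]_p} in mmol/L (vectorized
#'   over the state/infusion fields).
#' @examples
#' st <- patient_state(tbw = 34, na_plasma = 133, urine_osm = 766)
#' ev <- infusion_event(1.5, infusate(0.9))
#' round_display(voets_delta_na(st, ev))  # -1.9
#' @export
voets_delta_na <- function(state, infusion, tonicity_factor = 1.7) {
  st <- state_fields(state)
  ev <- infusion_fields(infusion)
  if (!is_number(tonicity_factor) || tonicity_factor <= 0) {
    stop_invalid("`tonicity_factor` must be a single positive number")
  }
  st$na_plasma * ev$volume / st$tbw *
    (tonicity_factor * ev$tonicity / st$urine_osm - 1)
}

#' Volume-generalized Adrogue-Madias equation
#'
#' The classic redistribution model, algebraically generalized from the
#' fixed 1 L of the original formulation to an arbitrary infused volume:
#' \deqn{\Delta [Na^+]_p = \frac{V_i ([Na^+]_i - [Na^+]_p)}{TBW + V_i}}
#' Equivalent to mixing `tbw` litres at `na_plasma` with `volume` litres at
#' the infusate sodium concentration; urine output is ignored. The
#' predicted final sodium therefore always lies strictly between
#' \eqn{[Na^+]_p} and \eqn{[Na^+]_i} when they differ.
#'
#' @inheritParams voets_delta_na
#' @return Unrounded predicted \eqn{\Delta [Na^+]_p} in mmol/L.
#' @examples
#' st <- patient_state(tbw = 34, na_plasma = 133, urine_osm = 766)
#' ev <- infusion_event(1.5, infusate(0.9))
#' round_display(adrogue_madias_delta_na(st, ev))  # +0.9
#' @export
adrogue_madias_delta_na <- function(state, infusion) {
  st <- state_fields(state)
  ev <- infusion_fields(infusion)
  ev$volume * (ev$na_conc - st$na_plasma) / (st$tbw + ev$volume)
}

#' Original Adrogue-Madias equation (1 L of infusate)
#'
#' \deqn{\Delta [Na^+]_p = \frac{[Na^+]_i - [Na^+]_p}{TBW + 1}}
#' Identical to [adrogue_madias_delta_na()] with `volume = 1`.
#'
#' @param state a [patient_state()].
#' @param infusate an [infusate()] object or NaCl mass-percent.
#' @return Predicted \eqn{\Delta [Na^+]_p} in mmol/L per litre infused.
#' @export
adrogue_madias_original <- function(state, infusate) {
  st <- state_fields(state)
  inf <- as_infusate(infusate)
  (inf$na_conc - st$na_plasma) / (st$tbw + 1)
}

#' Critical urine osmolality for a given infusate
#'
#' The urine osmolality at which the Voets prediction changes sign:
#' `tonicity_factor * tonicity`. Below it, the infusate raises the plasma
#' sodium; above it, the same infusate paradoxically lowers it (the classic
#' caution against normal saline in SIADH). For 0.9% saline the threshold
#' is 1.7 x 308 = 523.6 mOsmol/L, i.e. roughly 530 mOsmol/L.
#'
#' @param infusate an [infusate()] object, a NaCl mass-percent, or a bare
#'   numeric tonicity in mmol/L.
#' @param tonicity_factor see [voets_delta_na()].
#' @param tonicity_is_given set `TRUE` to interpret a numeric `infusate`
#'   argument as a tonicity rather than a mass-percent.
#' @return Critical urine osmolality in mOsmol/L.
#' @examples
#' critical_urine_osmolality(infusate(0.9))  # 523.6
#' @export
critical_urine_osmolality <- function(infusate, tonicity_factor = 1.7,
                                      tonicity_is_given = FALSE) {
  if (!is_number(tonicity_factor) || tonicity_factor <= 0) {
    stop_invalid("`tonicity_factor` must be a single positive number")
  }
  oi <- if (tonicity_is_given) {
    check_positive(infusate, "tonicity")
    infusate
  } else {
    as_infusate(infusate)$tonicity
  }
  tonicity_factor * oi
}

#' Predict the post-infusion plasma sodium
#'
#' Dispatches to the selected model and returns both the predicted change
#' and the predicted final sodium `na_plasma + delta_na`, unrounded. The
#' print method applies the 0.1 mmol/L display convention.
#'
#' @inheritParams voets_delta_na
#' @param model `"voets"` or `"adrogue_madias"` (alias `"am"`).
#' @return A data frame of class `"prediction_result"` with columns
#'   `model`, `na_initial`, `delta_na`, `na_final`.
#' @examples
#' st <- patient_state(tbw = 34, na_plasma = 133, urine_osm = 766)
#' predict_sodium(st, infusion_event(1.5, infusate(0.9)), "voets")
#' @export
predict_sodium <- function(state, infusion, model = c("voets", "adrogue_madias"),
                           tonicity_factor = 1.7) {
  model <- resolve_model(model[1L])
  st <- state_fields(state)
  delta <- switch(model,
    voets = voets_delta_na(state, infusion, tonicity_factor),
    adrogue_madias = adrogue_madias_delta_na(state, infusion)
  )
  na_final <- st$na_plasma + delta
  if (any(na_final < 0)) {
    warning("predicted final plasma sodium is negative; the model is a ",
            "first-order approximation and these inputs are outside its ",
            "domain of validity", call. = FALSE)
  }
  structure(
    data.frame(model = model, na_initial = st$na_plasma,
               delta_na = delta, na_final = na_final),
    class = c("prediction_result", "data.frame")
  )
}

resolve_model <- function(model) {
  m <- c(voets = "voets", adrogue_madias = "adrogue_madias",
         am = "adrogue_madias")[tolower(model)]
  if (is.na(m)) {
    stop_usage(sprintf("unknown model %s; use one of %s",
                       dQuote(model), paste(MODEL_NAMES, collapse = ", ")))
  }
  unname(m)
}

#' @export
print.prediction_result <- function(x, ...) {
  shown <- data.frame(
    model = x$model,
    na_initial = x$na_initial,
    delta_na = sprintf("%+.1f", round_display(x$delta_na)),
    na_final = sprintf("%.1f", round_display(x$na_final))
  )
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
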