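# Cohort-level validation of the prediction models: per-record unrounded
# predictions, Pearson correlation of predicted vs measured sodium change,
# exact t-based two-sided p-values, residual summaries, and the Fisher-z
# sample-size calculation used to size the study.

#' Pearson product-moment correlation
#'
#' Direct centered-sum implementation (not a wrapper around [stats::cor()],
#' which the test suite uses as an independent oracle). Requires at least
#' three pairs and two non-constant vectors.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return Correlation coefficient in \eqn{[-1, 1]}.
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop_usage("`x` and `y` must be numeric")
  if (length(x) != length(y)) stop_usage("`x` and `y` must have equal length")
  if (length(x) < 3L) stop_usage("need at least 3 pairs for a correlation")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("`x` and `y` must be finite")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    nat_stop("correlation is undefined for a constant vector",
             "natremia_undefined_correlation")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Exact small-sample test: \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} against a
#' Student t distribution with \eqn{n-2} degrees of freedom, two-sided. An
#' exact fit (`|r| == 1`) returns 0 with attribute `exact_fit = TRUE`.
#'
#' @param r correlation coefficient, `|r| <= 1`.
#' @param n number of pairs, `n >= 3`.
#' @return Two-sided p-value in \eqn{[0, 1]}.
#' @examples
#' pearson_p_two_sided(0.94, 15)  # well below 0.001
#' @export
pearson_p_two_sided <- function(r, n) {
  if (!is_number(r) || abs(r) > 1) stop_usage("`r` must be a number in [-1, 1]")
  if (!is_number(n) || n < 3 || n != round(n)) {
    stop_usage("`n` must be an integer >= 3")
  }
  if (abs(r) == 1) return(structure(0, exact_fit = TRUE))
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Sample size for detecting a correlation (Fisher z)
#'
#' Number of pairs needed to detect a true correlation `r_target` with a
#' two-sided test at significance `alpha` and the given power:
#' \deqn{n = \left(\frac{z_{1-\alpha/2} + z_{power}}{\mathrm{atanh}(r)}\right)^2 + 3}
#' For the conservative `r = 0.70` at `alpha = 0.05`, power 0.80, the raw
#' value is 13.43; the default `"nearest"` policy reports n = 13 (the
#' convention the validation study used), while `"ceiling"` gives the
#' strict guarantee n = 14. The raw value is always returned alongside.
#'
#' @param r_target true correlation to detect, `0 < |r_target| < 1`.
#' @param alpha two-sided significance level, default 0.05.
#' @param power target power, default 0.80.
#' @param method integer policy: `"nearest"` (default) or `"ceiling"`.
#' @return List of class `"sample_size"` with elements `n` (integer),
#'   `raw` (unrounded), `r_target`, `alpha`, `power`, `method`.
#' @examples
#' sample_size_for_correlation(0.70)$n  # 13
#' @export
sample_size_for_correlation <- function(r_target, alpha = 0.05, power = 0.80,
                                        method = c("nearest", "ceiling")) {
  method <- match.arg(method)
  if (!is_number(r_target) || abs(r_target) >= 1) {
    stop_usage("`r_target` must be a single number with |r| < 1")
  }
  if (r_target == 0) stop_usage("`r_target` = 0 requires an infinite sample")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_usage("`alpha` must be in (0, 1)")
  }
  if (!is_number(power) || power <= 0 || power >= 1) {
    stop_usage("`power` must be in (0, 1)")
  }
  C <- atanh(abs(r_target))  # Fisher z of the target correlation
  raw <- ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / C)^2 + 3
  n <- if (method == "nearest") as.integer(round(raw)) else as.integer(ceiling(raw))
  structure(list(n = n, raw = raw, r_target = r_target, alpha = alpha,
                 power = power, method = method),
            class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  cat(sprintf("n = %d (raw %.2f) to detect r = %.2f, two-sided alpha = %g, power = %g [%s]\n",
              x$n, x$raw, x$r_target, x$alpha, x$power, x$method))
  invisible(x)
}

#' Validate a prediction model against a measured cohort
#'
#' Computes unrounded per-record predictions with the chosen model, pairs
#' them with the measured change `na_final_mmol_l - na_initial_mmol_l`, and
#' summarizes agreement: Pearson r, exact two-sided p-value, residuals
#' (predicted minus measured), mean absolute error and signed bias. The
#' `pairs` element doubles as scatter-plot data (measured on one axis,
#' predicted on the other).
#'
#' @param x a [cohort()] with at least 3 records.
#' @param model `"voets"` or `"adrogue_madias"` (alias `"am"`).
#' @param tonicity_factor see [voets_delta_na()].
#' @return Object of class `"validation_report"`: list with `model`, `n`,
#'   `pairs` (data frame `record_id`, `measured`, `predicted`, `residual`),
#'   `pearson_r`, `p_value`, `mae`, `bias`.
#' @examples
#' validate_cohort(siadh_cohort(), "voets")
#' @export
validate_cohort <- function(x, model = c("voets", "adrogue_madias"),
                            tonicity_factor = 1.7) {
  stopifnot(inherits(x, "cohort"))
  model <- resolve_model(model[1L])
  rec <- x$records
  if (nrow(rec) < 3L) {
    stop_usage("cohort validation needs at least 3 records (r is undefined below that)")
  }
  preds <- cohort_predictions(rec, model, tonicity_factor)
  measured <- rec$na_final_mmol_l - rec$na_initial_mmol_l
  r <- pearson_r(measured, preds)
  p <- pearson_p_two_sided(r, length(measured))
  residual <- preds - measured
  structure(
    list(model = model, n = nrow(rec),
         pairs = data.frame(record_id = rec$record_id, measured = measured,
                            predicted = preds, residual = residual),
         pearson_r = r, p_value = as.numeric(p),
         mae = mean(abs(residual)), bias = mean(residual)),
    class = "validation_report"
  )
}

# unrounded per-record predictions for a cohort data frame
cohort_predictions <- function(rec, model, tonicity_factor = 1.7) {
  vapply(seq_len(nrow(rec)), function(i) {
    st <- patient_state(tbw = rec$tbw_l[i],
                        na_plasma = rec$na_initial_mmol_l[i],
                        urine_osm = rec$urine_osm_mosm_l[i])
    ev <- infusion_event(rec$infusate_volume_l[i],
                         infusate(rec$infusate_percent_nacl[i]))
    if (model == "voets") voets_delta_na(st, ev, tonicity_factor)
    else adrogue_madias_delta_na(st, ev)
  }, numeric(1))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> model %s, n = %d\n", x$model, x$n))
  cat(sprintf("  Pearson r = %.2f, two-sided p = %s (t test, df %d)\n",
              x$pearson_r,
              if (x$p_value < 0.001) "< 0.001" else sprintf("%.3f", x$p_value),
              x$n - 2L))
  cat(sprintf("  residuals (predicted - measured): MAE %.2f, bias %+.2f mmol/L\n",
              x$mae, x$bias))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param x a `"validation_report"` from [validate_cohort()].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "validation_report"))
  js <- jsonlite::toJSON(unclass(x), dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
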