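# Crystalloid NaCl infusates: mass-percent to sodium concentration and
# tonicity. NaCl molecular weight fixed at 58.44 g/mol; full dissociation
# (2 osmoles per mmol NaCl), potassium-free fluids only.

NACL_MW <- 58.44

#' Define a crystalloid NaCl infusate from its mass-percent
#'
#' Converts a NaCl mass fraction (g per 100 mL) into the sodium
#' concentration \eqn{[Na^+]_i} and tonicity \eqn{O_i} used by the
#' prediction models. The sodium concentration is
#' `percent * 10 * 1000 / 58.44` rounded to the nearest integer mmol/L, and
#' the tonicity is exactly twice that (ideal full dissociation of NaCl; the
#' fluids are potassium-free so no other solute contributes). Normal saline
#' (0.9%) gives 154 / 308 mmol/L and 2.5% hypertonic saline 428 / 856
#' mmol/L.
#'
#' @param nacl_percent NaCl mass fraction in g/100 mL; must be a single
#'   positive finite number.
#' @param label optional display label; defaults to e.g. `"0.9%-NaCl"`.
#' @return An object of class `"infusate"`: a list with elements `label`,
#'   `nacl_percent`, `na_conc` (mmol/L) and `tonicity` (mmol/L).
#' @examples
#' infusate(0.9)   # normal saline: [Na+]i 154, tonicity 308
#' infusate(2.5)   # hypertonic saline: [Na+]i 428, tonicity 856
#' @seealso [infusate_registry()], [load_infusates()]
#' @export
infusate <- function(nacl_percent, label = NULL) {
  if (!is_number(nacl_percent) || nacl_percent <= 0) {
    stop_invalid("`nacl_percent` must be a single positive finite number")
  }
  if (is.null(label)) {
    label <- sprintf("%s%%-NaCl", format(nacl_percent, trim = TRUE))
  }
  na_conc <- round(nacl_percent * 10 * 1000 / NACL_MW)
  structure(
    list(
      label = as.character(label)[1L],
      nacl_percent = nacl_percent,
      na_conc = na_conc,
      tonicity = 2 * na_conc
    ),
    class = "infusate"
  )
}

#' @export
print.infusate <- function(x, ...) {
  cat(sprintf("<infusate> %s: [Na+]i %d mmol/L, tonicity %d mmol/L\n",
              x$label, as.integer(x$na_conc), as.integer(x$tonicity)))
  invisible(x)
}

#' Built-in infusate registry
#'
#' The two saline strengths used in the bundled validation cohort. Arbitrary
#' strengths remain available through [infusate()].
#'
#' @return Named list of [infusate()] objects, keyed by label.
#' @examples
#' infusate_registry()[["0.9%-NaCl"]]$tonicity  # 308
#' @export
infusate_registry <- function() {
  specs <- list(infusate(0.9), infusate(2.5))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

#' Load infusate definitions from a config file
#'
#' Reads a two-column CSV (`label,nacl_percent`, header required) so that
#' additional fluids can be registered without code changes. Sodium
#' concentration and tonicity are derived, never read.
#'
#' @param path path to a CSV file with columns `label` and `nacl_percent`.
#' @return Named list of [infusate()] objects.
#' @export
load_infusates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "nacl_percent")
  if (!all(need %in% names(df))) {
    stop_parse(sprintf("infusate config must have columns %s",
                       paste(need, collapse = ", ")))
  }
  specs <- lapply(seq_len(nrow(df)), function(i) {
    p <- suppressWarnings(as.numeric(df$nacl_percent[i]))
    if (!is.finite(p)) {
      stop_parse(sprintf("row %d: non-numeric nacl_percent %s",
                         i, dQuote(df$nacl_percent[i])))
    }
    infusate(p, label = df$label[i])
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

# Resolve an infusate argument: an "infusate" object or a bare percent.
as_infusate <- function(x) {
  if (inherits(x, "infusate")) return(x)
  if (is_number(x)) return(infusate(x))
  stop_invalid("expected an `infusate` object or a NaCl mass-percent")
}
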