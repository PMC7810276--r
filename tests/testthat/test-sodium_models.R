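# Cell-level expected values below are the published per-measurement
# predictions (one-decimal display) or direct arithmetic from the closed
# forms; cohort inputs come from the bundled fixture rows.

test_that("Voets equation reproduces published per-measurement predictions", {
  cases <- list(
    # na, vi, tbw, pct, ou, expected (1 dp, half away from zero)
    list(na = 133, vi = 1.5,  tbw = 34, pct = 0.9, ou = 766, exp = -1.9),
    list(na = 127, vi = 0.10, tbw = 25, pct = 2.5, ou = 677, exp = +0.6),
    list(na = 122, vi = 0.15, tbw = 29, pct = 2.5, ou = 345, exp = +2.0),
    list(na = 106, vi = 0.15, tbw = 60, pct = 2.5, ou = 336, exp = +0.9)
  )
  for (cs in cases) {
    st <- patient_state(cs$tbw, cs$na, cs$ou)
    ev <- infusion_event(cs$vi, infusate(cs$pct))
    expect_equal(round_display(voets_delta_na(st, ev)), cs$exp)
  }
  # unrounded value for measurement 1: 133*1.5/34*(523.6/766 - 1)
  st1 <- patient_state(34, 133, 766)
  ev1 <- infusion_event(1.5, infusate(0.9))
  expect_equal(voets_delta_na(st1, ev1),
               133 * 1.5 / 34 * (1.7 * 308 / 766 - 1), tolerance = 1e-12)
})

test_that("modified Adrogue-Madias reproduces published predictions", {
  cases <- list(
    list(na = 133, vi = 1.5,  tbw = 34, pct = 0.9, exp = +0.9),
    list(na = 127, vi = 0.10, tbw = 25, pct = 2.5, exp = +1.2),
    list(na = 128, vi = 1.5,  tbw = 27, pct = 0.9, exp = +1.4),
    list(na = 122, vi = 0.15, tbw = 29, pct = 2.5, exp = +1.6)
  )
  for (cs in cases) {
    st <- patient_state(cs$tbw, cs$na, 500)  # Ou unused by this model
    ev <- infusion_event(cs$vi, infusate(cs$pct))
    expect_equal(round_display(adrogue_madias_delta_na(st, ev)), cs$exp)
  }
})

test_that("original 1 L Adrogue-Madias matches its published cells and the Vi = 1 case", {
  expect_equal(round_display(adrogue_madias_original(
    patient_state(37, 132, 702), infusate(0.9))), +0.6)
  expect_equal(round_display(adrogue_madias_original(
    patient_state(25, 128, 660), infusate(0.9))), +1.0)
  # isotonic-to-plasma infusate changes nothing
  st <- patient_state(40, 154, 500)
  expect_identical(adrogue_madias_original(st, infusate(0.9)), 0)
})

test_that("modified A-M equals the two-compartment mass-balance oracle", {
  # oracle: mix TBW litres at [Na+]p with Vi litres at [Na+]i, take the
  # new concentration minus the old
  inputs <- random_inputs(1000)
  for (i in seq_len(nrow(inputs))) {
    with(inputs[i, ], {
      st <- patient_state(tbw, na_plasma, urine_osm)
      inf <- infusate(0.9); inf$na_conc <- na_inf; inf$tonicity <- 2 * na_inf
      ev <- infusion_event(volume, inf)
      got <- adrogue_madias_delta_na(st, ev)
      oracle <- (tbw * na_plasma + volume * na_inf) / (tbw + volume) - na_plasma
      expect_equal(got, oracle, tolerance = 1e-10)
      # original equation is the Vi = 1 special case, exactly
      ev1 <- ev; ev1$volume <- 1
      expect_identical(adrogue_madias_delta_na(st, ev1),
                       adrogue_madias_original(st, inf))
      # predicted final sodium is bounded strictly between plasma and infusate
      if (na_inf != na_plasma) {
        final <- na_plasma + got
        expect_gt(final, min(na_plasma, na_inf))
        expect_lt(final, max(na_plasma, na_inf))
      }
    })
  }
})

test_that("Voets prediction is exactly linear in the infused volume", {
  inputs <- random_inputs(200, seed = 7)
  for (i in seq_len(nrow(inputs))) {
    with(inputs[i, ], {
      st <- patient_state(tbw, na_plasma, urine_osm)
      base <- voets_delta_na(st, infusion_event(volume, infusate(0.9)))
      for (k in c(0.25, 2, 7.5)) {
        expect_equal(voets_delta_na(st, infusion_event(k * volume, infusate(0.9))),
                     k * base, tolerance = 1e-12)
      }
    })
  }
})

test_that("Voets sign rule pivots at the critical urine osmolality", {
  inf <- infusate(0.9)
  crit <- critical_urine_osmolality(inf)  # 1.7 * 308
  expect_equal(crit, 523.6, tolerance = 1e-12)
  expect_equal(critical_urine_osmolality(infusate(2.5)), 1455.2,
               tolerance = 1e-12)
  expect_identical(critical_urine_osmolality(300, tonicity_factor = 1,
                                             tonicity_is_given = TRUE), 300)

  st_at <- patient_state(40, 130, crit)
  ev <- infusion_event(1, inf)
  expect_equal(voets_delta_na(st_at, ev), 0, tolerance = 1e-12)
  for (eps in c(0.5, 5, 50, 200)) {
    expect_gt(voets_delta_na(patient_state(40, 130, crit - eps), ev), 0)
    expect_lt(voets_delta_na(patient_state(40, 130, crit + eps), ev), 0)
  }
  # strictly decreasing in Ou
  ou_grid <- seq(100, 1200, by = 50)
  deltas <- vapply(ou_grid, function(ou)
    voets_delta_na(patient_state(40, 130, ou), ev), numeric(1))
  expect_true(all(diff(deltas) < 0))
})

test_that("invalid physiological inputs are rejected", {
  expect_error(patient_state(0, 130, 500), class = "natremia_invalid_input")
  expect_error(patient_state(40, -1, 500), class = "natremia_invalid_input")
  expect_error(patient_state(40, 130, 0), class = "natremia_invalid_input")
  expect_error(infusion_event(0, infusate(0.9)), class = "natremia_invalid_input")
  st <- patient_state(40, 130, 500)
  ev <- infusion_event(1, infusate(0.9))
  expect_error(voets_delta_na(st, ev, tonicity_factor = 0),
               class = "natremia_invalid_input")
  expect_error(voets_delta_na(list(), ev), class = "natremia_invalid_input")
})

test_that("predict_sodium dispatches and keeps na_final consistent", {
  st <- patient_state(34, 133, 766)
  ev <- infusion_event(1.5, infusate(0.9))
  pv <- predict_sodium(st, ev, "voets")
  expect_equal(pv$na_final, 133 + pv$delta_na, tolerance = 1e-12)
  expect_equal(round_display(pv$na_final), 131.1)
  pa <- predict_sodium(st, ev, "am")
  expect_identical(pa$model, "adrogue_madias")
  expect_error(predict_sodium(st, ev, "nonsense"),
               class = "natremia_usage_error")
  # zero-delta case: final equals initial
  st0 <- patient_state(40, 130, 523.6)
  p0 <- predict_sodium(st0, infusion_event(1, infusate(0.9)), "voets")
  expect_equal(p0$na_final, 130, tolerance = 1e-12)
  # extreme inputs may predict negative sodium: warn, never clamp
  st_x <- patient_state(1, 10, 10000)
  expect_warning(predict_sodium(st_x, infusion_event(30, infusate(0.9)), "voets"),
                 "negative")
})

test_that("display rounding is half away from zero at 0.1 mmol/L", {
  expect_equal(round_display(c(-1.85, 1.85, 0.25, -0.25, 1.449)),
               c(-1.9, 1.9, 0.3, -0.3, 1.4))
})
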