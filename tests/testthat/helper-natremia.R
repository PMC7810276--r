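# Shared fixtures built in code.

# a tiny, fully valid 3-record cohort data frame
tiny_cohort_df <- function() {
  data.frame(
    record_id = 1:3,
    sex = c("male", "female", "female"),
    age_y = c(70, 80, 65),
    weight_kg = c(60, 50, 64),
    tbw_l = c(36, 25, 32),
    infusate_volume_l = c(1.0, 0.5, 0.15),
    infusate_percent_nacl = c(0.9, 0.9, 2.5),
    na_initial_mmol_l = c(130, 128, 121),
    na_final_mmol_l = c(129, 128, 122),
    urine_osm_mosm_l = c(600, 480, 350),
    causative_condition = c("a", "b", "c"),
    stringsAsFactors = FALSE
  )
}

# random valid model inputs under a fixed seed, as a data frame
random_inputs <- function(n, seed = 2024) {
  withr::with_seed(seed, data.frame(
    na_plasma = runif(n, 100, 145),
    tbw = runif(n, 20, 70),
    urine_osm = runif(n, 100, 1200),
    volume = runif(n, 0.05, 3),
    na_inf = runif(n, 30, 600)
  ))
}
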