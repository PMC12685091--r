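# shared fixtures: the generating truth and small canned datasets
tt <- default_truth()

# single wild-type arm, engrafted 5e5 cells, biweekly observations
wt_arm_spec <- function(n_mice = 8) {
  list(arm_id = "wt", cells = 5e5, days = seq(6, 20, by = 2),
       n_mice = n_mice)
}

# one checkpoint-disrupted arm with a single labelled RT event
kort_arm_spec <- function(day = 12, dose = 8, A = 15.32,
                          label = "A_d12_8Gy") {
  ev <- label_activation(treatment_event(day, dose = dose, A = A), label)
  list(arm_id = sprintf("kort_d%d", day), cells = 5e5,
       schedule = treatment_schedule(ev), days = seq(6, 20, by = 2))
}
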