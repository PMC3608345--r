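# Canonical variable orderings shared across the package (sourced first).

.predictor_labels <- c("height", "weight", "sk_suprailiac", "sk_horiz_abdominal", "phv")
.response_labels <- c("fm", "bmc", "lst")

.cohort_vars <- c(
  "height", "weight", "seating_height", "age", "phv",
  "sk_suprailiac", "sk_horiz_abdominal", "fm", "bmc", "lst"
)
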