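# Independent oracles and shared fixtures, kept deliberately separate from
# the implementation paths they check.

# Term-by-term maturity-offset evaluation (independent arithmetic).
phv_oracle <- function(age, height, seating_height, weight) {
  leg <- height - seating_height
  terms <- c(
    -9.236,
    0.0002708 * leg * seating_height,
    -0.001663 * age * leg,
    0.007216 * age * seating_height,
    0.02292 * (weight / height * 100)
  )
  sum(terms)
}

# Published coefficient values as independently keyed-in vectors.
published_beta_fixture <- function() {
  rbind(
    height = c(fm = -0.0857, bmc = 0.0032, lst = 0.0820),
    weight = c(0.3139, 0.0392, 0.6419),
    sk_suprailiac = c(0.1970, -0.0095, -0.1964),
    sk_horiz_abdominal = c(0.2350, -0.0105, -0.2321),
    phv = c(-0.6571, 0.0525, 0.7047)
  )
}

# The printed worked-example inputs.
worked_example_record <- function() {
  anthropometric_record(
    height = 148.3, weight = 40.0,
    sk_suprailiac = 18.7, sk_horiz_abdominal = 20.0, phv = -1.6
  )
}

# Small random regression problem (well-conditioned), for property loops.
random_problem <- function(n, p, m = 3L, noise = 1) {
  X <- matrix(stats::rnorm(n * p, sd = 2), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  B <- matrix(stats::rnorm(p * m), p, m)
  Y <- X %*% B + matrix(stats::rnorm(n * m, sd = noise), n, m)
  colnames(Y) <- paste0("y", seq_len(m))
  list(X = X, Y = Y, B = B)
}

# Printed study quantities reused across tests (development sample, n = 408).
printed_press <- c(fm = 1162.433, bmc = 15.37255, lst = 1280.083)
printed_r2_press <- c(fm = 0.9490, bmc = 0.9402, lst = 0.9804)
printed_r2 <- c(fm = 0.9808, bmc = 0.9930, lst = 0.9981)
printed_see <- c(fm = 1.666, bmc = 0.192, lst = 1.748)
printed_sd <- c(fm = 7.5, bmc = 0.8, lst = 12.7)
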