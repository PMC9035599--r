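# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# explicit geometric series for the compounded passive detection probability
series_P_L <- function(p, tau) {
  sum(p * (1 - p)^(0:(tau - 1)))
}

# closed form of the critical interaction-gain threshold, valid when the
# benefit is increasing in alpha at the threshold (maximum attained at
# alpha = 1)
delta_closed_form <- function(rho_lm, tau, prior = 1 / 3) {
  x <- prior * rho_lm
  (1 - (1 - x)^tau) / x
}

# brute-force pure Nash enumeration for a 2x2 bimatrix game: check every
# profile against every unilateral deviation
nash_brute_force <- function(R, C) {
  out <- list()
  for (i in 1:2) {
    for (j in 1:2) {
      if (R[i, j] >= R[3 - i, j] && C[i, j] >= C[i, 3 - j]) {
        strict <- R[i, j] > R[3 - i, j] && C[i, j] > C[i, 3 - j]
        out[[length(out) + 1]] <- c(i = i, j = j, strict = strict)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(), j = integer(), strict = logical()))
  }
  as.data.frame(do.call(rbind, out))
}

random_bimatrix <- function(allow_ties = TRUE) {
  vals <- if (allow_ties && stats::runif(1) < 0.3) {
    sample(1:3, 8, replace = TRUE)  # ties likely
  } else {
    stats::rnorm(8)
  }
  list(R = matrix(vals[1:4], 2, 2), C = matrix(vals[5:8], 2, 2))
}

fig6_probs <- function() reduced_probs(u = 0.04, rho_lm = 0.1, w = 3.5)

# a fast world for dynamics tests (not the study conditions)
small_world <- function(...) world_config(trial_steps = 1500L, ...)
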