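#' Per-encounter detection probabilities
#'
#' Container for the four probabilities that a focal player detects the
#' partner during a single encounter with them, indexed by the strategy pair:
#' the focal player's strategy first (L = engage less, M = engage more), the
#' partner's second. So `rho_lm` is the probability that a passively sensing
#' player detects an actively engaging partner.
#'
#' @param rho_ll,rho_lm,rho_ml,rho_mm Probabilities in `[0, 1]`.
#' @return An object of class `pcp_probs`.
#' @seealso [reduced_probs()] for the (u, rho_LM, w) parameterization.
#' @examples
#' detection_probs(0.04, 0.1, 0.04, 0.35)
#' @export
detection_probs <- function(rho_ll, rho_lm, rho_ml, rho_mm) {
  check_prob(rho_ll)
  check_prob(rho_lm)
  check_prob(rho_ml)
  check_prob(rho_mm)
  structure(
    list(rho_ll = rho_ll, rho_lm = rho_lm, rho_ml = rho_ml, rho_mm = rho_mm),
    class = "pcp_probs"
  )
}

#' Reduced (u, rho_LM, w) parameterization of detection probabilities
#'
#' Collapses the four per-encounter detection probabilities to three numbers:
#' `u = rho_LL = rho_ML`, the probability of detecting a non-engaging partner
#' (taken to be independent of one's own strategy, since a non-engaging
#' partner offers very little interaction to probe), and
#' `w = rho_MM / rho_LM`, the multiplicative gain of engaging with a partner
#' who is also engaging.
#'
#' @param u Probability of detecting an L-playing partner, either strategy.
#' @param rho_lm Probability that a passive player detects an engaging partner.
#' @param w Interaction-gain ratio (`rho_mm = w * rho_lm`); requires
#'   `w * rho_lm <= 1`.
#' @return A [detection_probs()] object.
#' @examples
#' reduced_probs(u = 0.04, rho_lm = 0.1, w = 3.5)
#' @export
reduced_probs <- function(u = 0.04, rho_lm = 0.1, w = 3.5) {
  check_prob(u)
  check_prob(rho_lm)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0) {
    stop("`w` must be a single non-negative number.", call. = FALSE)
  }
  if (w * rho_lm > 1 + 1e-12) {
    stop("Invalid reduced parameterization: w * rho_lm = ",
         format(w * rho_lm), " exceeds 1, so rho_MM would not be a ",
         "probability.", call. = FALSE)
  }
  detection_probs(rho_ll = u, rho_lm = rho_lm, rho_ml = u,
                  rho_mm = w * rho_lm)
}

#' @export
print.pcp_probs <- function(x, ...) {
  cat("<pcp_probs>  per-encounter detection probabilities\n")
  cat(sprintf("  rho_LL = %-8.4g rho_LM = %-8.4g\n", x$rho_ll, x$rho_lm))
  cat(sprintf("  rho_ML = %-8.4g rho_MM = %-8.4g\n", x$rho_ml, x$rho_mm))
  if (isTRUE(all.equal(x$rho_ll, x$rho_ml)) && x$rho_lm > 0) {
    cat(sprintf("  reduced form: u = %.4g, w = %.4g\n",
                x$rho_ll, x$rho_mm / x$rho_lm))
  }
  invisible(x)
}

#' Encounter parameters
#'
#' The tunable quantities of one modelled encounter: the partner's engagement
#' probability `alpha` (probability of playing M rather than L on any given
#' encounter), the integer time-cost ratio `tau` between an M-probe and an
#' L-probe, and the prior probability that an encountered unknown object is
#' the partner's avatar (1/3 in the standard three-object PCP world).
#'
#' @param alpha Engagement probability (may be a vector) in `[0, 1]`.
#' @param tau Integer time-cost ratio, `>= 1`.
#' @param prior Prior probability that the encountered object is the partner,
#'   in `(0, 1]`.
#' @return An object of class `pcp_params`.
#' @examples
#' encounter_params(alpha = 0.5, tau = 3)
#' @export
encounter_params <- function(alpha, tau = 3L, prior = 1 / 3) {
  if (!is.numeric(alpha) || length(alpha) < 1L || anyNA(alpha) ||
      any(alpha < 0 | alpha > 1)) {
    stop("`alpha` must be numeric in [0, 1].", call. = FALSE)
  }
  check_tau(tau)
  if (!is.numeric(prior) || length(prior) != 1L || is.na(prior) ||
      prior <= 0 || prior > 1) {
    stop("`prior` must be a single probability in (0, 1].", call. = FALSE)
  }
  structure(list(alpha = alpha, tau = as.integer(tau), prior = prior),
            class = "pcp_params")
}

#' @export
print.pcp_params <- function(x, ...) {
  cat("<pcp_params>\n")
  cat("  alpha:", format(x$alpha, digits = 4), "\n")
  cat("  tau:  ", x$tau, "\n")
  cat("  prior:", format(x$prior, digits = 4), "\n")
  invisible(x)
}

#' Single-probe detection probabilities p_L and p_M
#'
#' `p_L()` is the probability of finding the partner during one passive
#' (L) probe of an unknown object, `p_M()` during one active (M) probe:
#' \deqn{p_L(\alpha) = prior\,((1-\alpha)\rho_{LL} + \alpha\rho_{LM})}
#' \deqn{p_M(\alpha) = prior\,((1-\alpha)\rho_{ML} + \alpha\rho_{MM})}
#' where `alpha` is the partner's engagement probability and the prior is the
#' probability that the unknown object is the partner at all.
#'
#' @param params An [encounter_params()] object (vector `alpha` allowed).
#' @param probs A [detection_probs()] object.
#' @return Numeric vector of probabilities, one per `alpha`.
#' @examples
#' p_L(encounter_params(1), reduced_probs())
#' @export
p_L <- function(params, probs) {
  validate_model_inputs(params, probs)
  params$prior *
    ((1 - params$alpha) * probs$rho_ll + params$alpha * probs$rho_lm)
}

#' @rdname p_L
#' @export
p_M <- function(params, probs) {
  validate_model_inputs(params, probs)
  params$prior *
    ((1 - params$alpha) * probs$rho_ml + params$alpha * probs$rho_mm)
}

#' Constant-time-cost detection probabilities P_L and P_M
#'
#' One M-probe costs `tau` times the duration of an L-probe, so the fair
#' comparison gives the L-player `tau` independent probes: the compounded
#' probability is the geometric series
#' \deqn{P_L = p_L \sum_{i=0}^{\tau-1} (1-p_L)^i = 1 - (1-p_L)^\tau,}
#' while the M-player spends the whole budget on one probe, \eqn{P_M = p_M}.
#' The closed form is used; it agrees with the explicit series to numerical
#' precision.
#'
#' @inheritParams p_L
#' @return Numeric vector of probabilities.
#' @examples
#' P_L(encounter_params(1, tau = 3), reduced_probs())
#' @export
P_L <- function(params, probs) {
  compound_L(p_L(params, probs), params$tau)
}

#' @rdname P_L
#' @export
P_M <- function(params, probs) {
  p_M(params, probs)
}

# closed form of the tau-term geometric series
compound_L <- function(p, tau) {
  1 - (1 - p)^tau
}

#' Benefit of engaging at constant time cost
#'
#' The benefit `g` of playing M over playing L during one encounter, holding
#' total time spent fixed: \eqn{g(\alpha) = P_M(\alpha) - P_L(\alpha)}.
#' Positive values mean active engagement is the better use of the time
#' budget against a partner who engages with probability `alpha`.
#'
#' @inheritParams p_L
#' @return Numeric vector in `[-1, 1]`, one value per `alpha`.
#' @examples
#' params <- encounter_params(alpha = c(0, 0.5, 1), tau = 3)
#' benefit_g(params, reduced_probs(u = 0.04, rho_lm = 0.1, w = 3.5))
#' @export
benefit_g <- function(params, probs) {
  P_M(params, probs) - P_L(params, probs)
}

#' Joint detection probability under mixed strategies
#'
#' Probability that the focal player detects the partner at constant time
#' cost when the focal player engages with probability `alpha_a` and the
#' partner with probability `alpha_b`:
#' \deqn{P(\alpha_A, \alpha_B) = \alpha_A P_M(\alpha_B) +
#'   (1-\alpha_A) P_L(\alpha_B).}
#'
#' @param alpha_a Focal player's engagement probability (vectorized).
#' @param alpha_b Partner's engagement probability (vectorized, recycled).
#' @param probs A [detection_probs()] object.
#' @param tau Integer time-cost ratio.
#' @param prior Prior probability that an encountered object is the partner.
#' @return Numeric vector of probabilities.
#' @examples
#' joint_P(1, 1, reduced_probs(), tau = 3)
#' @export
joint_P <- function(alpha_a, alpha_b, probs, tau = 3L, prior = 1 / 3) {
  if (!is.numeric(alpha_a) || anyNA(alpha_a) ||
      any(alpha_a < 0 | alpha_a > 1)) {
    stop("`alpha_a` must be numeric in [0, 1].", call. = FALSE)
  }
  params_b <- encounter_params(alpha_b, tau = tau, prior = prior)
  alpha_a * P_M(params_b, probs) + (1 - alpha_a) * P_L(params_b, probs)
}

#' Critical interaction-gain threshold delta
#'
#' The critical value of the interaction-gain ratio `w` below which passive
#' sensing is (weakly) the better strategy for every partner engagement level
#' `alpha`. Operationally, delta is the infimum of `w` such that
#' `benefit_g > 0` for some `alpha` in `[0, 1]`; it is located by scanning an
#' alpha grid for the maximum benefit and bisecting on `w` (the maximum
#' benefit is strictly increasing in `w`). The Assurance structure of the
#' encounter game requires `w > delta`.
#'
#' When the benefit is increasing in `alpha` at the threshold, delta has the
#' closed form \deqn{\delta = \frac{1 - (1 - prior\,\rho_{LM})^\tau}
#' {prior\,\rho_{LM}},} which is used as an independent oracle in the test
#' suite, not as the implementation.
#'
#' @param rho_lm Probability that a passive player detects an engaging
#'   partner; must be in `(0, 1]`.
#' @param tau Integer time-cost ratio.
#' @param u Probability of detecting a non-engaging partner.
#' @param prior Prior probability that an encountered object is the partner.
#' @param tol Bisection tolerance on `w`.
#' @param n_alpha Size of the alpha grid scanned for a positive benefit.
#' @return The threshold value of `w` (a single number). The threshold is a
#'   property of the model formulas; for large `rho_lm * tau` it can exceed
#'   the feasibility bound `1 / rho_lm`, in which case no admissible
#'   probability set attains a positive benefit.
#' @examples
#' delta_threshold(rho_lm = 0.1, tau = 3, u = 0.04)
#' @export
delta_threshold <- function(rho_lm, tau, u, prior = 1 / 3, tol = 1e-6,
                            n_alpha = 201L) {
  if (!is.numeric(rho_lm) || length(rho_lm) != 1L || is.na(rho_lm) ||
      rho_lm <= 0 || rho_lm > 1) {
    stop("`rho_lm` must be in (0, 1]; the threshold is undefined at 0.",
         call. = FALSE)
  }
  check_tau(tau)
  check_prob(u)
  alpha_grid <- seq(0, 1, length.out = n_alpha)
  # raw model arithmetic: delta is a property of the formulas, so w sweeps
  # past the feasibility bound w * rho_lm <= 1 when the threshold lies there
  max_g <- function(w) {
    p_l <- prior * ((1 - alpha_grid) * u + alpha_grid * rho_lm)
    p_m <- prior * ((1 - alpha_grid) * u + alpha_grid * w * rho_lm)
    max(p_m - (1 - (1 - p_l)^tau))
  }
  eps <- 1e-12  # guards against roundoff in 1 - (1 - p)^tau at tau = 1
  lo <- 0
  hi <- tau + 1
  # max_g is strictly increasing in w; max_g(tau + 1) > 0 always since
  # (1 - x)^tau > 1 - tau * x for x in (0, 1)
  if (max_g(lo) > eps) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (max_g(mid) > eps) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Engagement cutoff alpha*
#'
#' The partner engagement level above which active engagement beats passive
#' sensing at constant time cost: the root of `g(alpha) = 0` in `[0, 1]`.
#' Returns `NA` when the benefit does not change sign on `[0, 1]` (in
#' particular for `w < delta`, where passive sensing is always at least as
#' good). The cutoff decreases as `w` grows.
#'
#' @param probs A [detection_probs()] object.
#' @param tau Integer time-cost ratio.
#' @param prior Prior probability that an encountered object is the partner.
#' @param tol Root-finding tolerance.
#' @return The cutoff value of alpha, or `NA_real_` if none exists.
#' @examples
#' alpha_cutoff(reduced_probs(u = 0.04, rho_lm = 0.1, w = 3.5), tau = 3)
#' @export
alpha_cutoff <- function(probs, tau, prior = 1 / 3, tol = 1e-9) {
  check_tau(tau)
  g_of <- function(a) {
    benefit_g(encounter_params(a, tau = tau, prior = prior), probs)
  }
  grid <- seq(0, 1, length.out = 201L)
  gg <- g_of(grid)
  if (all(gg <= 0) || all(gg >= 0)) {
    if (gg[1] > 0) return(0)
    return(NA_real_)
  }
  i <- which(diff(sign(gg)) != 0)[1]
  uniroot(g_of, lower = grid[i], upper = grid[i + 1], tol = tol)$root
}

# ---- internal validation helpers -------------------------------------------

check_prob <- function(x) {
  nm <- deparse(substitute(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", nm, "` must be a single probability in [0, 1].", call. = FALSE)
  }
  invisible(x)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 1 ||
      tau != round(tau)) {
    stop("`tau` must be a single integer >= 1.", call. = FALSE)
  }
  invisible(tau)
}

validate_model_inputs <- function(params, probs) {
  if (!inherits(params, "pcp_params")) {
    stop("`params` must be created with encounter_params().", call. = FALSE)
  }
  if (!inherits(probs, "pcp_probs")) {
    stop("`probs` must be created with detection_probs() or reduced_probs().",
         call. = FALSE)
  }
  invisible(TRUE)
}
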