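#' World configuration for the PCP simulator
#'
#' Geometry, kinematics and scoring parameters of the simulated
#' perceptual-crossing world: a shared ring on which each of the two
#' participants moves an avatar and feels, through binary haptic contact,
#' their own static object, the partner's avatar, and the partner's shadow
#' (the partner's avatar displaced by a fixed offset; touching it stimulates
#' the toucher but not the shadowed partner).
#'
#' Behavioural parameters: while scanning, an agent moves at `scan_speed`
#' with persistent direction, reversing at rate `turn_prob` per step. A
#' contact onset opens a probing episode: passive (L, `probe_window` steps,
#' sensing in passing) or, with the agent's engagement probability, engaged
#' (M, `tau * probe_window` steps) in which the agent oscillates about the
#' stimulation site at `engage_speed`, reversing on contact loss and staying
#' within `engage_range` of the anchor. An episode scores a detection only
#' if the probed object is the partner's avatar and the stimulation was rich
#' enough: at least `onset_min` distinct contact onsets and at least
#' `contact_frac` of the nominal window spent in contact.
#'
#' @param ring_length Ring circumference, distance units.
#' @param object_width Contact radius: two objects touch when their centres
#'   are closer than this.
#' @param shadow_offset Displacement of each shadow from its avatar.
#' @param scan_speed Scanning/passive speed, units per step.
#' @param engage_speed Engaged oscillation speed, units per step.
#' @param turn_prob Per-step probability of reversing while scanning.
#' @param engage_range Confinement radius of engaged oscillation.
#' @param speed_jitter Standard deviation of per-step velocity noise. This
#'   is what lets two slowly converging passive agents rattle in and out of
#'   contact instead of crossing cleanly, giving mutual non-engagement its
#'   small but non-zero detection rate.
#' @param probe_window Passive probe length in steps; an engaged probe lasts
#'   `tau` times as long.
#' @param tau Integer time-cost ratio of an M-probe to an L-probe.
#' @param trial_steps Steps per trial.
#' @param onset_min Minimum distinct contact onsets for a detection.
#' @param contact_frac Minimum fraction of the nominal window in contact.
#' @param static_pos Positions of the two private static objects.
#' @return A validated list of class `pcp_world_config`.
#' @examples
#' world_config()
#' @export
world_config <- function(ring_length = 600, object_width = 4,
                         shadow_offset = 48, scan_speed = 2,
                         engage_speed = 2.5, turn_prob = 0.01,
                         engage_range = 30, speed_jitter = 0.5,
                         probe_window = 50, tau = 3L,
                         trial_steps = 6000L, onset_min = 3L,
                         contact_frac = 0.3, static_pos = c(150, 450)) {
  check_tau(tau)
  stopifnot(
    ring_length > 2 * (object_width + shadow_offset),
    object_width > 0, shadow_offset > 0, scan_speed > 0, engage_speed > 0,
    turn_prob >= 0, turn_prob <= 1, engage_range > 0, speed_jitter >= 0,
    probe_window >= 1, trial_steps >= 1, onset_min >= 1,
    contact_frac >= 0, contact_frac <= 1, length(static_pos) == 2,
    all(static_pos >= 0), all(static_pos < ring_length)
  )
  structure(
    list(ring_length = ring_length, object_width = object_width,
         shadow_offset = shadow_offset, scan_speed = scan_speed,
         engage_speed = engage_speed, turn_prob = turn_prob,
         engage_range = engage_range, speed_jitter = speed_jitter,
         probe_window = as.integer(probe_window),
         tau = as.integer(tau), trial_steps = as.integer(trial_steps),
         onset_min = as.integer(onset_min), contact_frac = contact_frac,
         static_pos = static_pos[1], static_pos_b = static_pos[2]),
    class = "pcp_world_config"
  )
}

#' @export
print.pcp_world_config <- function(x, ...) {
  cat("<pcp_world_config>\n")
  flat <- unlist(x)
  for (nm in names(flat)) cat(sprintf("  %-14s %g\n", nm, flat[[nm]]))
  invisible(x)
}

cond_index <- function(alpha_a, alpha_b) {
  # stable RNG stream index per strategy pair
  as.integer(1 + 2 * round(alpha_a * 100) + round(alpha_b * 100)) %% 1000L
}

#' Simulate one PCP trial
#'
#' Runs a single seeded trial of the agent-based world and returns the
#' per-step trace and the encounter log.
#'
#' @param config A [world_config()].
#' @param alpha_a,alpha_b Engagement probabilities of the two agents.
#' @param seed Integer seed; together with `trial` it determines one
#'   independent RNG stream per agent.
#' @param trial Trial index (varies the streams under a fixed seed).
#' @param keep_trace Return the per-step trace (positions, contact flags,
#'   modes)?
#' @return A list of class `pcp_trial` with `episodes` (tibble: one row per
#'   probing episode with object identity, strategy, onset and contact
#'   counts, and the detection outcome) and, if requested, `trace` (tibble:
#'   step, positions, contact bitmasks with bits static/avatar/shadow, and
#'   modes 0 = scan, 1 = passive probe, 2 = engaged).
#' @examples
#' tr <- simulate_trial(world_config(trial_steps = 500), 1, 1, seed = 1)
#' head(tr$episodes)
#' @export
simulate_trial <- function(config, alpha_a, alpha_b, seed, trial = 1L,
                           keep_trace = TRUE) {
  stopifnot(inherits(config, "pcp_world_config"))
  res <- .sim_trial_cpp(unclass(config), alpha_a, alpha_b,
                        as.integer(seed), cond_index(alpha_a, alpha_b),
                        as.integer(trial), keep_trace)
  episodes <- tibble::as_tibble(res$episodes)
  episodes$object <- c("static", "avatar", "shadow")[episodes$object]
  episodes$strategy <- c("L", "M")[episodes$strategy + 1L]
  n_trunc <- sum(episodes$truncated)
  if (n_trunc > 0) {
    message(n_trunc, " episode(s) truncated at trial end and excluded from ",
            "detection scoring.")
  }
  out <- list(episodes = episodes, config = config,
              alpha = c(a = alpha_a, b = alpha_b))
  if (keep_trace) {
    tr <- res$trace
    colnames(tr) <- c("step", "pos_a", "pos_b", "contact_a", "contact_b",
                      "mode_a", "mode_b")
    out$trace <- tibble::as_tibble(tr)
  }
  structure(out, class = "pcp_trial")
}

#' @export
print.pcp_trial <- function(x, ...) {
  cat(sprintf("<pcp_trial>  alpha = (%g, %g), %d episodes\n",
              x$alpha[["a"]], x$alpha[["b"]], nrow(x$episodes)))
  invisible(x)
}

#' Wilson score interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Named vector `lower`, `upper`.
#' @keywords internal
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Estimate per-encounter detection probabilities from simulation
#'
#' Runs `n_trials` seeded trials for each pure strategy pair (L,L), (L,M),
#' (M,L), (M,M) -- i.e. engagement probabilities 0 and 1 -- and estimates
#' each detection probability as the fraction of the focal agent's
#' avatar-probing episodes that scored a detection, with Wilson 95%
#' confidence intervals.
#'
#' @param config A [world_config()].
#' @param n_trials Trials per strategy pair.
#' @param seed Integer seed; results are fully reproducible given
#'   (config, n_trials, seed).
#' @return A tibble of class `pcp_rho_estimates`: one row per strategy pair
#'   with detections, avatar-encounter counts, `rho_hat` and CI bounds.
#' @examples
#' \donttest{
#' estimate_rhos(world_config(), n_trials = 50, seed = 1)
#' }
#' @export
estimate_rhos <- function(config, n_trials = 500L, seed = 1L) {
  stopifnot(inherits(config, "pcp_world_config"), n_trials >= 1)
  pairs <- tibble::tibble(
    pair = c("LL", "LM", "ML", "MM"),
    alpha_a = c(0, 0, 1, 1),
    alpha_b = c(0, 1, 0, 1)
  )
  counts <- purrr::pmap(pairs, function(pair, alpha_a, alpha_b) {
    cts <- .sim_counts_cpp(unclass(config), alpha_a, alpha_b,
                           as.integer(seed), cond_index(alpha_a, alpha_b),
                           as.integer(n_trials))
    if (cts[["encounters"]] == 0) {
      stop("No avatar encounters in condition ", pair,
           ": the world configuration is inadequate (increase trial_steps ",
           "or n_trials, or revisit the geometry).", call. = FALSE)
    }
    ci <- wilson_ci(cts[["detections"]], cts[["encounters"]])
    tibble::tibble(
      pair = pair,
      detections = cts[["detections"]],
      encounters = cts[["encounters"]],
      episodes = cts[["episodes"]],
      rho_hat = cts[["detections"]] / cts[["encounters"]],
      ci_lower = ci[["lower"]],
      ci_upper = ci[["upper"]]
    )
  })
  out <- dplyr::bind_rows(counts)
  structure(out, class = c("pcp_rho_estimates", class(out)),
            n_trials = n_trials, seed = seed, config = config)
}

#' Confidence-interval plot of estimated detection probabilities
#'
#' @param object An [estimate_rhos()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcp_rho_estimates <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pair, .data$rho_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::labs(x = "strategy pair (focal, partner)",
                  y = expression(hat(rho))) +
    ggplot2::theme_minimal()
}
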