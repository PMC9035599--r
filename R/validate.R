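#' End-to-end validation: does the simulated world induce an Assurance game?
#'
#' Runs the full pipeline: estimates the four per-encounter detection
#' probabilities from the agent-based simulator, plugs them into the
#' encounter model, binarizes the induced game at the pure strategies
#' actually simulated (alpha 0 and 1), and checks the model's standing
#' assumptions against the estimates:
#' * `rho_MM > rho_LM`: an engaging partner is easier to detect when
#'   engaging back;
#' * `rho_LM >= rho_LL`: an engaging partner is at least as detectable as a
#'   passive one even to a passive observer;
#' * `rho_LL ~= rho_ML` (overlapping Wilson intervals): time spent engaging
#'   a passive partner does not help;
#' * `w > delta`: the interaction gain clears the critical threshold, so
#'   the induced game should classify as Assurance.
#'
#' @param config A [world_config()].
#' @param n_trials Trials per strategy pair.
#' @param seed Integer seed.
#' @param prior Prior probability that an encountered object is the partner
#'   used when plugging the estimates into the model (1/3 in the standard
#'   three-object world).
#' @return A list of class `pcp_validation`: `rhos` (the
#'   [estimate_rhos()] tibble), `probs`, `game`, `classification`, `delta`,
#'   `w_hat`, and a `checks` tibble. `glance()` gives a one-row summary.
#' @examples
#' \donttest{
#' validate_model(world_config(), n_trials = 50, seed = 1)
#' }
#' @export
validate_model <- function(config, n_trials = 500L, seed = 1L,
                           prior = 1 / 3) {
  if (n_trials < 30) {
    warning("n_trials = ", n_trials, " gives wide intervals; interpret the ",
            "assumption checks loosely.", call. = FALSE)
  }
  rhos <- estimate_rhos(config, n_trials = n_trials, seed = seed)
  est <- setNames(rhos$rho_hat, rhos$pair)
  probs <- detection_probs(rho_ll = est[["LL"]], rho_lm = est[["LM"]],
                           rho_ml = est[["ML"]], rho_mm = est[["MM"]])
  w_hat <- if (est[["LM"]] > 0) est[["MM"]] / est[["LM"]] else NA_real_
  delta <- if (est[["LM"]] > 0) {
    delta_threshold(est[["LM"]], tau = config$tau, u = est[["LL"]],
                    prior = prior)
  } else {
    NA_real_
  }
  game <- binarize_game(probs, tau = config$tau, alpha_low = 0,
                        alpha_high = 1, prior = prior)
  classification <- suppressWarnings(classify_game(game))

  ci <- function(pair) {
    unlist(rhos[rhos$pair == pair, c("ci_lower", "ci_upper")])
  }
  overlap <- ci("LL")[1] <= ci("ML")[2] && ci("ML")[1] <= ci("LL")[2]
  checks <- tibble::tibble(
    check = c("rho_MM > rho_LM", "rho_LM >= rho_LL",
              "rho_LL ~= rho_ML (Wilson CIs overlap)", "w_hat > delta",
              "classification == assurance"),
    passed = c(est[["MM"]] > est[["LM"]],
               est[["LM"]] >= est[["LL"]],
               overlap,
               isTRUE(w_hat > delta),
               classification == "assurance")
  )
  structure(
    list(rhos = rhos, probs = probs, game = game,
         classification = classification, delta = delta, w_hat = w_hat,
         n_trials = n_trials, seed = seed, checks = checks),
    class = "pcp_validation"
  )
}

#' @export
print.pcp_validation <- function(x, ...) {
  cat("<pcp_validation>\n")
  cat(sprintf("  n_trials = %d per strategy pair, seed = %d\n",
              x$n_trials, x$seed))
  cat(sprintf("  rho_hat: LL = %.4f  LM = %.4f  ML = %.4f  MM = %.4f\n",
              x$probs$rho_ll, x$probs$rho_lm, x$probs$rho_ml, x$probs$rho_mm))
  cat(sprintf("  w_hat = %.3f, delta = %.3f\n", x$w_hat, x$delta))
  cat(sprintf("  induced game: %s\n", x$classification))
  ok <- ifelse(x$checks$passed, "ok", "FAILED")
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s\n", ok[i], x$checks$check[i]))
  }
  invisible(x)
}

#' @rdname validate_model
#' @param x A `pcp_validation` object.
#' @param ... Unused.
#' @export
glance.pcp_validation <- function(x, ...) {
  tibble::tibble(
    rho_ll = x$probs$rho_ll, rho_lm = x$probs$rho_lm,
    rho_ml = x$probs$rho_ml, rho_mm = x$probs$rho_mm,
    w_hat = x$w_hat, delta = x$delta,
    classification = x$classification,
    all_checks_passed = all(x$checks$passed),
    n_trials = x$n_trials, seed = x$seed
  )
}
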