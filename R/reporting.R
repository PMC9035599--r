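#' Load a flat configuration file
#'
#' Reads a flat YAML (or JSON) file of model/simulator parameters and merges
#' it under a list of overrides, with overrides winning. Used by the
#' command-line interface; exported so that scripted analyses can share
#' config files with it.
#'
#' @param path Path to a YAML or JSON file, or `NULL` for no file.
#' @param overrides Named list of values that take precedence (e.g. parsed
#'   command-line flags). `NULL` entries are dropped.
#' @return Named list of parameters.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  base <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("Config file not found: ", path,
                                 call. = FALSE)
    base <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (!is.list(base)) stop("Config file must contain a mapping.",
                             call. = FALSE)
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  modifyList(base, overrides)
}

#' Game report for a parameter set
#'
#' Builds the binarized encounter game from the reduced model parameters and
#' returns a JSON-ready report: payoffs, ordinal ranks, pure Nash equilibria
#' and the classification.
#'
#' @param u,rho_lm,w Reduced detection-probability parameters.
#' @param tau Integer time-cost ratio.
#' @param alpha_low,alpha_high Binarization.
#' @param prior Prior probability that an encountered object is the partner.
#' @return A list with elements `parameters`, `payoffs`, `ordinal_ranks`,
#'   `pure_nash`, `classification`.
#' @examples
#' game_report(u = 0.04, rho_lm = 0.1, w = 3.5, tau = 3)$classification
#' @export
game_report <- function(u = 0.04, rho_lm = 0.1, w = 3.5, tau = 3L,
                        alpha_low = 0.25, alpha_high = 0.75,
                        prior = 1 / 3) {
  probs <- reduced_probs(u, rho_lm, w)
  game <- binarize_game(probs, tau = tau, alpha_low = alpha_low,
                        alpha_high = alpha_high, prior = prior)
  ranks <- ordinal_ranks(game)
  list(
    parameters = list(u = u, rho_lm = rho_lm, w = w, tau = tau,
                      alpha_low = alpha_low, alpha_high = alpha_high,
                      prior = prior),
    payoffs = game$payoff_row,
    ordinal_ranks = ranks$row,
    pure_nash = as.data.frame(pure_nash(game)),
    classification = suppressWarnings(classify_game(game))
  )
}

#' Write a JSON report with provenance
#'
#' Serialises a report together with the resolved configuration and package
#' version, so a run can be reproduced from its output alone.
#'
#' @param report A list (e.g. from [game_report()] or [glance()]).
#' @param path Output path.
#' @param config Resolved configuration list to embed.
#' @param seed Seed used, if any.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, config = list(), seed = NULL) {
  payload <- list(
    provenance = list(
      package = "pcpgame",
      version = as.character(utils::packageVersion("pcpgame")),
      config = config,
      seed = seed
    ),
    report = report
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
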