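#' Binarize the encounter model into a symmetric 2x2 game
#'
#' Reduces the continuum of engagement probabilities to the two options
#' "low alpha" and "high alpha" and fills a 2x2 payoff matrix with the joint
#' detection probabilities at constant time cost: the cell for strategies
#' (s_A, s_B) holds `joint_P(alpha_A, alpha_B)` for the row player and
#' `joint_P(alpha_B, alpha_A)` for the column player, so the game is
#' symmetric by construction. The default representative values are the
#' quadrant centres 0.25 and 0.75; the corners (0, 1) are the fully
#' committed binarization.
#'
#' @param probs A [detection_probs()] object.
#' @param tau Integer time-cost ratio.
#' @param alpha_low,alpha_high Representative engagement probabilities,
#'   `0 <= alpha_low < alpha_high <= 1`.
#' @param prior Prior probability that an encountered object is the partner.
#' @return An object of class `pcp_game`: strategy labels, the row-player
#'   payoff matrix (column player's is its transpose), and the binarization.
#' @examples
#' game <- binarize_game(reduced_probs(0.04, 0.1, 3.5), tau = 3)
#' game
#' pure_nash(game)
#' classify_game(game)
#' @export
binarize_game <- function(probs, tau = 3L, alpha_low = 0.25,
                          alpha_high = 0.75, prior = 1 / 3) {
  if (!inherits(probs, "pcp_probs")) {
    stop("`probs` must be created with detection_probs() or reduced_probs().",
         call. = FALSE)
  }
  if (!is.numeric(alpha_low) || !is.numeric(alpha_high) ||
      length(alpha_low) != 1L || length(alpha_high) != 1L ||
      anyNA(c(alpha_low, alpha_high)) ||
      alpha_low < 0 || alpha_high > 1 || alpha_low >= alpha_high) {
    stop("Need 0 <= alpha_low < alpha_high <= 1.", call. = FALSE)
  }
  a <- c(alpha_low, alpha_high)
  payoff <- outer(a, a, function(ai, aj) {
    joint_P(ai, aj, probs, tau = tau, prior = prior)
  })
  labels <- c("low", "high")
  dimnames(payoff) <- list(row = labels, col = labels)
  new_pcp_game(payoff, labels,
               binarization = c(alpha_low = alpha_low,
                                alpha_high = alpha_high))
}

#' Construct a 2x2 game from payoff matrices
#'
#' Lower-level constructor used by [binarize_game()] and by tests: a 2x2
#' bimatrix game given the row player's payoff matrix and optionally an
#' asymmetric column player's matrix (defaults to the symmetric transpose).
#'
#' @param payoff_row 2x2 numeric matrix, row player's payoffs.
#' @param payoff_col 2x2 numeric matrix, column player's payoffs; default
#'   `t(payoff_row)` (symmetric game).
#' @param labels Character vector of two strategy names.
#' @return A `pcp_game` object.
#' @export
two_by_two_game <- function(payoff_row, payoff_col = t(payoff_row),
                            labels = c("low", "high")) {
  stopifnot(is.matrix(payoff_row), all(dim(payoff_row) == 2L),
            is.matrix(payoff_col), all(dim(payoff_col) == 2L),
            all(is.finite(payoff_row)), all(is.finite(payoff_col)),
            length(labels) == 2L)
  dimnames(payoff_row) <- dimnames(payoff_col) <- list(row = labels,
                                                       col = labels)
  new_pcp_game(payoff_row, labels, payoff_col = payoff_col)
}

new_pcp_game <- function(payoff_row, labels, payoff_col = t(payoff_row),
                         binarization = NULL) {
  structure(
    list(payoff_row = payoff_row, payoff_col = payoff_col,
         labels = labels,
         symmetric = isTRUE(all.equal(unname(payoff_col),
                                      unname(t(payoff_row)))),
         binarization = binarization),
    class = "pcp_game"
  )
}

#' @export
print.pcp_game <- function(x, digits = 4, ...) {
  cat("<pcp_game>", if (x$symmetric) "symmetric", "2x2 game\n")
  if (!is.null(x$binarization)) {
    cat(sprintf("  binarization: alpha_low = %g, alpha_high = %g\n",
                x$binarization[["alpha_low"]],
                x$binarization[["alpha_high"]]))
  }
  cells <- matrix(
    paste0(format(x$payoff_row, digits = digits), ", ",
           format(t(x$payoff_col), digits = digits)),
    2, 2, dimnames = list(x$labels, x$labels)
  )
  print(cells, quote = FALSE)
  invisible(x)
}

#' Pure-strategy Nash equilibria of a 2x2 game
#'
#' Enumerates all strategy profiles in which each player's strategy is a
#' (weakly) best response to the other's, annotating which are strict.
#'
#' @param game A `pcp_game` object.
#' @return A tibble with columns `row`, `col` (strategy labels) and `strict`.
#' @export
pure_nash <- function(game) {
  stopifnot(inherits(game, "pcp_game"))
  R <- game$payoff_row
  C <- game$payoff_col
  # best-response sets: for each opponent strategy, which own strategies
  # attain the maximum payoff
  br_row <- lapply(1:2, function(j) which(R[, j] == max(R[, j])))
  br_col <- lapply(1:2, function(i) which(C[i, ] == max(C[i, ])))
  profiles <- tidyr::expand_grid(i = 1:2, j = 1:2)
  is_ne <- purrr::map2_lgl(profiles$i, profiles$j, function(i, j) {
    i %in% br_row[[j]] && j %in% br_col[[i]]
  })
  strict <- purrr::map2_lgl(profiles$i, profiles$j, function(i, j) {
    length(br_row[[j]]) == 1L && length(br_col[[i]]) == 1L &&
      i == br_row[[j]] && j == br_col[[i]]
  })
  tibble::tibble(
    row = game$labels[profiles$i[is_ne]],
    col = game$labels[profiles$j[is_ne]],
    strict = strict[is_ne]
  )
}

#' Ordinal payoff ranks of a 2x2 game
#'
#' Ranks each player's four payoffs from 0 (worst) to 3 (best); tied
#' payoffs share their average rank and are flagged.
#'
#' @param game A `pcp_game` object.
#' @return A list with 2x2 matrices `row` and `col` of ranks and a logical
#'   `ties`.
#' @export
ordinal_ranks <- function(game) {
  stopifnot(inherits(game, "pcp_game"))
  rank0 <- function(m) {
    r <- matrix(rank(m, ties.method = "average") - 1, 2, 2,
                dimnames = dimnames(m))
    r
  }
  ties <- anyDuplicated(c(game$payoff_row)) > 0 ||
    anyDuplicated(c(game$payoff_col)) > 0
  list(row = rank0(game$payoff_row), col = rank0(game$payoff_col),
       ties = ties)
}

#' Classify a symmetric 2x2 game
#'
#' Classifies by equilibrium structure and Pareto ranking, invariant under
#' strictly increasing payoff transforms:
#' * `assurance` -- both same-strategy profiles are strict Nash equilibria
#'   and the (high, high) profile Pareto-dominates;
#' * `prisoners_dilemma` -- one strategy strictly dominates, yet the
#'   dominated symmetric profile Pareto-dominates the equilibrium;
#' * `dominance_solvable` -- one strategy strictly dominates and the
#'   equilibrium is not Pareto-dominated as above;
#' * `pure_coordination` -- both diagonal profiles are strict equilibria
#'   with equal payoffs (unreachable when all payoffs are distinct);
#' * `other` -- anything else, including games with tied payoffs (a warning
#'   is raised) and asymmetric games.
#'
#' @param game A `pcp_game` object.
#' @return A single character classification.
#' @export
classify_game <- function(game) {
  stopifnot(inherits(game, "pcp_game"))
  if (!game$symmetric) return("other")
  R <- game$payoff_row
  if (anyDuplicated(c(R)) > 0) {
    # equal diagonal strict equilibria would be pure coordination, but any
    # tie makes the ordinal structure ambiguous
    warning("Tied payoffs: classification is \"other\".", call. = FALSE)
    return("other")
  }
  ne <- pure_nash(game)
  diag_ne <- function(k) {
    any(ne$row == game$labels[k] & ne$col == game$labels[k] & ne$strict)
  }
  both_diag <- diag_ne(1) && diag_ne(2)
  if (both_diag && R[2, 2] > R[1, 1]) return("assurance")
  # strict dominance of strategy d over the other
  dominant <- NULL
  if (all(R[1, ] > R[2, ])) dominant <- 1L
  if (all(R[2, ] > R[1, ])) dominant <- 2L
  if (!is.null(dominant)) {
    dominated <- 3L - dominant
    if (R[dominated, dominated] > R[dominant, dominant]) {
      return("prisoners_dilemma")
    }
    return("dominance_solvable")
  }
  "other"
}

#' Tidiers for 2x2 games
#'
#' @name pcp_game_tidiers
#' @param x A `pcp_game` object.
#' @param ... Unused.
#' @return `tidy()`: one row per cell with both players' payoffs and
#'   ordinal ranks; `glance()`: a one-row summary with the classification
#'   and equilibrium count.
#' @export
tidy.pcp_game <- function(x, ...) {
  ranks <- ordinal_ranks(x)
  ne <- pure_nash(x)
  grid <- tidyr::expand_grid(i = 1:2, j = 1:2)
  tibble::tibble(
    row = x$labels[grid$i],
    col = x$labels[grid$j],
    payoff_row = x$payoff_row[cbind(grid$i, grid$j)],
    payoff_col = x$payoff_col[cbind(grid$i, grid$j)],
    rank_row = ranks$row[cbind(grid$i, grid$j)],
    rank_col = ranks$col[cbind(grid$i, grid$j)],
    nash = purrr::map2_lgl(.data$row, .data$col, function(r, c) {
      any(ne$row == r & ne$col == c)
    })
  )
}

#' @rdname pcp_game_tidiers
#' @export
glance.pcp_game <- function(x, ...) {
  ne <- pure_nash(x)
  tibble::tibble(
    classification = suppressWarnings(classify_game(x)),
    n_pure_nash = nrow(ne),
    n_strict_nash = sum(ne$strict),
    symmetric = x$symmetric
  )
}

#' Payoff-matrix tile plot for a 2x2 game
#'
#' @param object A `pcp_game` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcp_game <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$payoff_row)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.4f, %.4f%s", .data$payoff_row, .data$payoff_col,
                      ifelse(.data$nash, "\nNash", ""))
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "goldenrod") +
    ggplot2::labs(x = "partner strategy", y = "focal strategy",
                  fill = "P(detect)") +
    ggplot2::theme_minimal()
}
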