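#' Payoff landscape over two model parameters
#'
#' Evaluates the engagement benefit `g` or the joint detection probability
#' `P` on a rectangular grid over two swept parameters, holding the rest
#' fixed. This is the data behind the model's heatmap figures: `g` over
#' (alpha, w), `g` over (alpha, rho_lm), and `P` over (alpha_a, alpha_b).
#'
#' @param x,y Names of the swept parameters, among `"alpha"`, `"alpha_a"`,
#'   `"alpha_b"`, `"w"`, `"rho_lm"`. `value = "g"` sweeps any two of
#'   `alpha`, `w`, `rho_lm`; `value = "P"` sweeps `alpha_a` and `alpha_b`.
#' @param x_values,y_values Strictly increasing numeric grids.
#' @param fixed Named list of the held-constant parameters (`u`, `rho_lm`,
#'   `w`, `tau`, `prior`, and for `value = "P"` nothing further).
#' @param value `"g"` (benefit of engaging) or `"P"` (joint detection
#'   probability).
#' @return A tibble of class `pcp_landscape` with columns `x`, `y`, `value`
#'   and attributes `x_name`, `y_name`, `value_name`, `fixed`.
#' @examples
#' land <- payoff_landscape(
#'   "alpha", "w", seq(0, 1, 0.1), seq(1, 6, 0.5),
#'   fixed = list(u = 0.04, rho_lm = 0.1, tau = 3)
#' )
#' head(land)
#' @export
payoff_landscape <- function(x, y, x_values, y_values,
                             fixed = list(), value = c("g", "P")) {
  value <- match.arg(value)
  sweep_names <- if (value == "g") c("alpha", "w", "rho_lm") else
    c("alpha_a", "alpha_b")
  if (!is.character(x) || !is.character(y) || !(x %in% sweep_names) ||
      !(y %in% sweep_names) || x == y) {
    stop("`x` and `y` must be two distinct parameters among: ",
         paste(sweep_names, collapse = ", "), call. = FALSE)
  }
  check_grid(x_values, "x_values")
  check_grid(y_values, "y_values")

  defaults <- list(u = 0.04, rho_lm = 0.1, w = 3.5, tau = 3L, prior = 1 / 3,
                   alpha = NULL)
  fixed <- modifyList(defaults, fixed)

  grid <- tidyr::expand_grid(y = y_values, x = x_values)
  pars <- list()
  pars[[x]] <- grid$x
  pars[[y]] <- grid$y

  if (value == "g") {
    alpha  <- pars$alpha %||% fixed$alpha
    if (is.null(alpha)) {
      stop("`alpha` must be swept or supplied in `fixed` for value = \"g\".",
           call. = FALSE)
    }
    w      <- pars$w %||% fixed$w
    rho_lm <- pars$rho_lm %||% fixed$rho_lm
    v <- g_vectorized(alpha, rho_lm, w, fixed$u, fixed$tau, fixed$prior)
  } else {
    probs <- reduced_probs(fixed$u, fixed$rho_lm, fixed$w)
    v <- joint_P(pars$alpha_a, pars$alpha_b, probs,
                 tau = fixed$tau, prior = fixed$prior)
  }

  out <- tibble::tibble(x = grid$x, y = grid$y, value = v)
  structure(out,
            class = c("pcp_landscape", class(out)),
            x_name = x, y_name = y, value_name = value,
            fixed = fixed[setdiff(names(fixed), c(x, y))])
}

# benefit g with all of (alpha, rho_lm, w) allowed to be vectors
g_vectorized <- function(alpha, rho_lm, w, u, tau, prior) {
  rho_mm <- w * rho_lm
  if (any(rho_mm > 1 + 1e-12)) {
    stop("Grid contains w * rho_lm > 1 (rho_MM would exceed 1).",
         call. = FALSE)
  }
  p_l <- prior * ((1 - alpha) * u + alpha * rho_lm)
  p_m <- prior * ((1 - alpha) * u + alpha * rho_mm)
  p_m - (1 - (1 - p_l)^tau)
}

check_grid <- function(v, nm) {
  if (!is.numeric(v) || length(v) < 1L || anyNA(v) ||
      (length(v) > 1L && any(diff(v) <= 0))) {
    stop("`", nm, "` must be a strictly increasing numeric grid.",
         call. = FALSE)
  }
  invisible(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a landscape grid as CSV
#'
#' Writes the swept grid with a header naming the two swept parameters and
#' the value, in full double precision so that re-reading reproduces the
#' in-memory values exactly.
#'
#' @param landscape A [payoff_landscape()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  stopifnot(inherits(landscape, "pcp_landscape"))
  df <- data.frame(
    x = formatC(landscape$x, format = "g", digits = 17),
    y = formatC(landscape$y, format = "g", digits = 17),
    value = formatC(landscape$value, format = "g", digits = 17)
  )
  names(df) <- c(attr(landscape, "x_name"), attr(landscape, "y_name"),
                 attr(landscape, "value_name"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back an exported landscape grid
#'
#' @param path CSV file written by [write_landscape_csv()].
#' @return A tibble with the two swept parameters and the value column.
#' @export
read_landscape_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Reproduce the model's figure grids
#'
#' Writes the four canonical landscape grids as `fig3.csv` ... `fig6.csv`:
#' benefit `g` over (alpha, w) at `rho_lm = 0.1`; `g` over (alpha, rho_lm)
#' at `w = 3.5` and at `w = 2.8`; and the joint detection probability `P`
#' over (alpha_a, alpha_b). All use `u = 0.04`, `tau = 3`, `prior = 1/3`.
#'
#' @param out_dir Output directory (created if missing).
#' @param n Grid points per axis.
#' @param rho_lm_max Upper bound of the swept `rho_lm` grid. The default
#'   0.28 keeps the `w = 2.8` panel informative (the region where engaging
#'   pays only reaches down to `rho_lm` around 0.205 at that `w`, so a
#'   shorter axis would show no positive region at all) while keeping
#'   `w * rho_lm <= 1` on the `w = 3.5` panel.
#' @return Named character vector of the four file paths, invisibly.
#' @export
reproduce_figures <- function(out_dir = ".", n = 201L, rho_lm_max = 0.28) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  alphas <- seq(0, 1, length.out = n)
  ws     <- seq(1, 6, length.out = n)
  rhos   <- seq(0.01, rho_lm_max, length.out = n)
  grids <- list(
    fig3 = payoff_landscape("alpha", "w", alphas, ws,
                            fixed = list(u = 0.04, rho_lm = 0.1, tau = 3)),
    fig4 = payoff_landscape("alpha", "rho_lm", alphas, rhos,
                            fixed = list(u = 0.04, w = 3.5, tau = 3)),
    fig5 = payoff_landscape("alpha", "rho_lm", alphas, rhos,
                            fixed = list(u = 0.04, w = 2.8, tau = 3)),
    fig6 = payoff_landscape("alpha_a", "alpha_b", alphas, alphas,
                            fixed = list(u = 0.04, rho_lm = 0.1, w = 3.5,
                                         tau = 3),
                            value = "P")
  )
  paths <- vapply(names(grids), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_landscape_csv(grids[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' @export
print.pcp_landscape <- function(x, ...) {
  cat(sprintf("<pcp_landscape>  %s over (%s, %s), %d cells\n",
              attr(x, "value_name"), attr(x, "x_name"), attr(x, "y_name"),
              nrow(x)))
  NextMethod()
}

#' Heatmap of a payoff landscape
#'
#' @param object A [payoff_landscape()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcp_landscape <- function(object, ...) {
  vname <- attr(object, "value_name")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = attr(object, "x_name"), y = attr(object, "y_name"),
                  fill = vname) +
    ggplot2::theme_minimal()
  if (vname == "g") {
    p <- p + ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                           high = "firebrick", midpoint = 0)
  } else {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}
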