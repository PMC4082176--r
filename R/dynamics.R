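#' One year of the population, compartment by compartment
#'
#' A population state holds the four compartment tallies of one model year:
#' healthy (`w`), mentally ill (`x`), deaths from other causes occurring in
#' that year (`y`) and suicides occurring in that year (`z`). In the
#' replacement model `y` and `z` are annual flows, not cumulative stocks:
#' last year's deaths re-enter as healthy newborns one step later, which is
#' exactly what keeps `w + x + y + z` constant. In the no-replacement
#' variant they accumulate.
#'
#' @param w healthy count (>= 0).
#' @param x mentally ill count (>= 0).
#' @param y other-cause deaths (>= 0).
#' @param z suicides (>= 0).
#' @param year integer year index.
#' @return A named numeric vector `c(w, x, y, z)` of class
#'   `"population_state"` with a `year` attribute.
#' @export
population_state <- function(w, x, y = 0, z = 0, year = 0) {
  s <- c(w = w, x = x, y = y, z = z)
  if (any(!is.finite(s)) || any(s < 0))
    stop("compartment counts must be finite and non-negative")
  structure(s, year = as.integer(year), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "Population state, year %d: healthy %s | ill %s | other-cause deaths %s | suicides %s (total %s)\n",
    attr(x, "year"),
    format(x[["w"]], big.mark = ","), format(x[["x"]], big.mark = ","),
    format(x[["y"]], big.mark = ","), format(x[["z"]], big.mark = ","),
    format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Advance the population by one year
#'
#' Applies the one-year evolution map of the illness-death model. With
#' `replacement = TRUE` (the default), all of last year's deaths re-enter
#' the healthy compartment, so the flows are
#' \deqn{w' = (1 - p_{21} - p_{31} - p_{41})\,w + p_{12}\,x + y + z}
#' \deqn{x' = p_{21}\,w + (1 - p_{12} - p_{32} - p_{42})\,x}
#' \deqn{y' = p_{31}\,w + p_{32}\,x, \qquad z' = p_{41}\,w + p_{42}\,x}
#' and the total \eqn{w + x + y + z} is conserved. With
#' `replacement = FALSE` the death compartments are absorbing and
#' accumulate (`y' = y + p31 w + p32 x`, `z' = z + p41 w + p42 x`); the
#' living population `w + x` then decays exponentially whenever any death
#' probability is positive.
#'
#' @param state a [population_state].
#' @param params a [transition_params] object (or a `"suicide_model"`,
#'   whose parameters are used).
#' @param replacement logical; replace deaths by healthy newborns?
#' @return The year-(n+1) [population_state].
#' @examples
#' s0 <- population_state(w = 6850000, x = 150000)
#' step_population(s0, transition_params())
#' @export
step_population <- function(state, params, replacement = TRUE) {
  if (inherits(params, "suicide_model")) params <- params$params
  params <- validate_parameters(params)
  if (!inherits(state, "population_state"))
    state <- population_state(state[["w"]], state[["x"]],
                              state[["y"]], state[["z"]])
  p <- params
  w <- state[["w"]]; x <- state[["x"]]; y <- state[["y"]]; z <- state[["z"]]
  w_stay <- 1 - p[["p21"]] - p[["p31"]] - p[["p41"]]
  x_stay <- 1 - p[["p12"]] - p[["p32"]] - p[["p42"]]
  if (replacement) {
    population_state(
      w = w_stay * w + p[["p12"]] * x + y + z,
      x = p[["p21"]] * w + x_stay * x,
      y = p[["p31"]] * w + p[["p32"]] * x,
      z = p[["p41"]] * w + p[["p42"]] * x,
      year = attr(state, "year") + 1L)
  } else {
    population_state(
      w = w_stay * w + p[["p12"]] * x,
      x = p[["p21"]] * w + x_stay * x,
      y = y + p[["p31"]] * w + p[["p32"]] * x,
      z = z + p[["p41"]] * w + p[["p42"]] * x,
      year = attr(state, "year") + 1L)
  }
}

#' Deterministic trajectory of the compartment tallies
#'
#' Iterates the one-year map for a fixed number of years and returns the
#' whole path. This is the expectation dynamics; for a stochastic
#' realization see [simulate.suicide_model()].
#'
#' @param object a `"suicide_model"`.
#' @param years number of years to project.
#' @param init optional starting [population_state]; defaults to the
#'   model's initial state (everyone alive, `initial_ill` mentally ill).
#' @param replacement logical, as in [step_population()].
#' @param ... unused.
#' @return A data frame with columns `year, w, x, y, z`, one row per year
#'   (year 0 is the initial state), of class `c("suicide_trajectory",
#'   "data.frame")`.
#' @examples
#' head(predict(suicide_model(), years = 5))
#' @export
predict.suicide_model <- function(object, years = 100, init = NULL,
                                  replacement = TRUE, ...) {
  if (is.null(init)) init <- .initial_state(object)
  years <- as.integer(years)
  if (years < 1) stop("years must be >= 1")
  out <- matrix(NA_real_, nrow = years + 1, ncol = 4,
                dimnames = list(NULL, c("w", "x", "y", "z")))
  s <- init
  out[1, ] <- as.numeric(s)
  for (i in seq_len(years)) {
    s <- step_population(s, object$params, replacement = replacement)
    out[i + 1, ] <- as.numeric(s)
  }
  df <- data.frame(year = attr(init, "year") + 0:years, out)
  class(df) <- c("suicide_trajectory", "data.frame")
  attr(df, "Q0") <- object$Q0
  df
}

#' Power iteration to the stationary state
#'
#' Iterates the replacement dynamics until the largest per-compartment
#' change in one step falls below `tol * Q0`. The result must (and, for
#' valid parameters, does) agree with the closed-form stationary
#' distribution of [equilibrium()]; the iteration is the model's own
#' cross-check of that formula.
#'
#' @param model a `"suicide_model"`.
#' @param init optional starting [population_state].
#' @param tol convergence tolerance as a fraction of `Q0` (default 1e-10).
#' @param max_years iteration cap (default 100,000); exceeding it is an
#'   error reporting the final residual.
#' @param keep_trajectory logical; retain the visited states? (Off by
#'   default to keep long runs cheap.)
#' @return A list of class `"suicide_equilibrium_iter"` with elements
#'   `fractions` (named `w, x, y, z`, summing to 1), `state` (the final
#'   [population_state]), `years` (steps taken), `residual` (last maximum
#'   per-compartment change, as a fraction of `Q0`) and, if requested,
#'   `trajectory`.
#' @examples
#' it <- iterate_to_equilibrium(suicide_model())
#' it$fractions
#' @export
iterate_to_equilibrium <- function(model, init = NULL, tol = 1e-10,
                                   max_years = 100000,
                                   keep_trajectory = FALSE) {
  stopifnot(inherits(model, "suicide_model"))
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  if (max_years < 1) stop("max_years must be >= 1")
  if (is.null(init)) init <- .initial_state(model)
  Q0 <- sum(init)
  s <- as.numeric(init)
  p <- model$params
  traj <- if (keep_trajectory) list(s) else NULL
  w_stay <- 1 - p[["p21"]] - p[["p31"]] - p[["p41"]]
  x_stay <- 1 - p[["p12"]] - p[["p32"]] - p[["p42"]]
  years <- 0L
  repeat {
    s_new <- c(w_stay * s[1] + p[["p12"]] * s[2] + s[3] + s[4],
               p[["p21"]] * s[1] + x_stay * s[2],
               p[["p31"]] * s[1] + p[["p32"]] * s[2],
               p[["p41"]] * s[1] + p[["p42"]] * s[2])
    years <- years + 1L
    resid <- max(abs(s_new - s)) / Q0
    if (keep_trajectory) traj[[years + 1L]] <- s_new
    s <- s_new
    if (resid < tol) break
    if (years >= max_years)
      stop(sprintf(
        "no convergence after %d years (residual %.3e, tolerance %.3e)",
        years, resid, tol))
  }
  out <- list(
    fractions = stats::setNames(s / Q0, c("w", "x", "y", "z")),
    state = population_state(s[1], s[2], s[3], s[4], year = years),
    years = years, residual = resid)
  if (keep_trajectory) {
    m <- do.call(rbind, traj)
    out$trajectory <- data.frame(year = 0:years,
                                 w = m[, 1], x = m[, 2],
                                 y = m[, 3], z = m[, 4])
    class(out$trajectory) <- c("suicide_trajectory", "data.frame")
    attr(out$trajectory, "Q0") <- Q0
  }
  class(out) <- "suicide_equilibrium_iter"
  out
}

#' @export
print.suicide_equilibrium_iter <- function(x, ...) {
  cat(sprintf(
    "Power iteration converged in %d years (residual %.2e of Q0)\n",
    x$years, x$residual))
  cat("  stationary fractions (w, x, y, z): ",
      paste(format(x$fractions, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Plot the approach to the stationary state
#'
#' Shows the mentally ill share of the population year by year together
#' with its closed-form stationary value, the headline trajectory of the
#' model (the Hong Kong run rises from 2.14% to about 3.4%).
#'
#' @param x a `"suicide_model"`.
#' @param years horizon in years.
#' @param ... passed to [graphics::plot()].
#' @return The trajectory data frame, invisibly.
#' @export
plot.suicide_model <- function(x, years = 150, ...) {
  tr <- predict(x, years = years)
  eq <- equilibrium(x)
  share <- 100 * tr$x / x$Q0
  graphics::plot(tr$year, share, type = "l", lwd = 2,
                 xlab = "year", ylab = "mentally ill (% of population)",
                 main = "Approach to the stationary state", ...)
  graphics::abline(h = 100 * eq$fractions[["x"]], lty = 2, col = "grey40")
  graphics::legend("bottomright", bty = "n",
                   legend = c("iterated dynamics", "closed-form equilibrium"),
                   lty = c(1, 2), lwd = c(2, 1),
                   col = c("black", "grey40"))
  invisible(tr)
}
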