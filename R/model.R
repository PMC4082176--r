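#' Four-state Markov suicide dynamics model
#'
#' Builds the discrete-time Markov illness-death model of suicide dynamics
#' for a closed population with death-replacement. The population is split
#' into four compartments: healthy (`w`), mentally ill (`x`), deaths from
#' other causes in the current year (`y`) and suicides in the current year
#' (`z`). Each year, a fraction `p21` of the healthy become mentally ill,
#' `p31` die of other causes and `p41` die by suicide; of the mentally ill,
#' `p12` recover, `p32` die of other causes and `p42` die by suicide. Under
#' replacement dynamics, all deaths of year *n* re-enter the population as
#' healthy newborns in year *n* + 1, so the total `w + x + y + z` is
#' conserved at `Q0` and the chain has a unique stationary distribution
#' (see [equilibrium()]).
#'
#' @param params a [transition_params] object; defaults to the Hong Kong
#'   2012 estimates.
#' @param Q0 total population size (living plus current-year deaths);
#'   defaults to 7 million (Hong Kong, 2012).
#' @param initial_ill number of mentally ill at year 0 used as the default
#'   starting state for trajectories and simulations; defaults to 150,000
#'   (psychiatric service caseload), i.e. an initial ill share of 2.14%.
#'
#' @return An object of class `"suicide_model"`: a list with elements
#'   `params`, `Q0` and `initial_ill`. Methods: [print.suicide_model()],
#'   [summary.suicide_model()], [coef.suicide_model()],
#'   [predict.suicide_model()], [plot.suicide_model()],
#'   [simulate.suicide_model()].
#'
#' @examples
#' m <- suicide_model()
#' equilibrium(m)
#' summary(m)
#' @seealso [equilibrium()], [sensitivity()], [sensitivity_table()],
#'   [simulate.suicide_model()]
#' @export
suicide_model <- function(params = transition_params(), Q0 = 7e6,
                          initial_ill = 150000) {
  params <- validate_parameters(params)
  if (!is.numeric(Q0) || length(Q0) != 1 || !is.finite(Q0) || Q0 <= 0)
    stop("Q0 must be a single positive number")
  if (!is.numeric(initial_ill) || initial_ill < 0 || initial_ill > Q0)
    stop("initial_ill must lie in [0, Q0]")
  structure(list(params = params, Q0 = Q0, initial_ill = initial_ill),
            class = "suicide_model")
}

#' @export
print.suicide_model <- function(x, ...) {
  cat("Markov illness-death model of suicide dynamics (with replacement)\n")
  cat(sprintf("  Total population Q0: %s   initial mentally ill: %s (%.2f%%)\n",
              format(x$Q0, big.mark = ","),
              format(x$initial_ill, big.mark = ","),
              100 * x$initial_ill / x$Q0))
  print(x$params)
  invisible(x)
}

#' @rdname suicide_model
#' @param object,x a `"suicide_model"` object.
#' @param ... unused.
#' @export
coef.suicide_model <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(object$params))
}

#' Summarise a suicide dynamics model
#'
#' Computes the stationary distribution, the derived per-capita rates and
#' the sensitivity coefficients of the equilibrium suicide count, and
#' prints them in the units epidemiologists use (suicides per 100,000,
#' other-cause deaths per 1,000, percent mentally ill).
#'
#' @param object a `"suicide_model"` object.
#' @param reference_dp41 probability decrement used for the headline
#'   intervention projection (default 1e-5, i.e. 1 per 100,000).
#' @param ... unused.
#' @return An object of class `"summary.suicide_model"` containing the
#'   model, its [equilibrium()] and its [sensitivity()] report.
#' @export
summary.suicide_model <- function(object, reference_dp41 = 1e-5, ...) {
  structure(list(model = object,
                 equilibrium = equilibrium(object),
                 sensitivity = sensitivity(object, dp = reference_dp41)),
            class = "summary.suicide_model")
}

#' @export
print.summary.suicide_model <- function(x, ...) {
  print(x$model)
  cat("\n")
  print(x$equilibrium)
  cat("\n")
  print(x$sensitivity)
  invisible(x)
}

# default starting state: everyone alive, prevalent ill stock from the model
.initial_state <- function(model) {
  population_state(w = model$Q0 - model$initial_ill, x = model$initial_ill,
                   y = 0, z = 0, year = 0)
}
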