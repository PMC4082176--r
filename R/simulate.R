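#' Stochastic cohort microsimulation of the replacement dynamics
#'
#' Simulates the illness-death model year by year as a stochastic process:
#' each year the healthy compartment's exits are drawn from a single
#' four-outcome multinomial over (stay, become ill, die of other causes,
#' die by suicide) with the model's probabilities, and likewise for the
#' mentally ill compartment over (stay, recover, die of other causes, die
#' by suicide). All deaths of year *n* re-enter the healthy compartment in
#' year *n* + 1, so the total of living people plus current-year deaths is
#' exactly `Q0` every year. One integer seed controls the entire run;
#' identical seeds give identical tallies.
#'
#' Per-compartment multinomial draws are the aggregate of independent
#' per-individual categorical draws, so event counts are binomial and the
#' re-estimated probabilities of [estimate_transitions()] carry exact
#' binomial standard errors.
#'
#' @param object a `"suicide_model"` (starting state: `Q0 - initial_ill`
#'   healthy, `initial_ill` mentally ill, no deaths yet).
#' @param nsim number of independent replicate runs (default 1).
#' @param seed integer seed; required for reproducibility, optional
#'   otherwise.
#' @param years number of years to simulate (default 200).
#' @param ... unused.
#' @return For `nsim = 1`, a data frame of class `c("cohort_tallies",
#'   "data.frame")` with one row per year and columns `year`,
#'   `healthy_start`, `ill_start`, the six event tallies
#'   (`healthy_to_ill`, `healthy_to_death_other`, `healthy_to_suicide`,
#'   `ill_to_recovered`, `ill_to_death_other`, `ill_to_suicide`) and
#'   `replacements` (deaths of the previous year re-entering as healthy).
#'   For `nsim > 1`, a list of such data frames. Attributes record `Q0`
#'   and the seed.
#' @examples
#' m <- suicide_model(Q0 = 1e5, initial_ill = 2143)
#' tal <- simulate(m, seed = 1, years = 50)
#' head(tal)
#' @seealso [estimate_transitions()] to recover the probabilities from the
#'   tallies.
#' @export
simulate.suicide_model <- function(object, nsim = 1, seed = NULL,
                                   years = 200, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (nsim == 1) return(.simulate_one(object, years, seed))
  out <- lapply(seq_len(nsim), function(i) .simulate_one(object, years, seed))
  out
}

.simulate_one <- function(model, years, seed) {
  years <- as.integer(years)
  if (is.na(years) || years < 1) stop("years must be an integer >= 1")
  Q0 <- model$Q0
  if (Q0 < 1) stop("Q0 must be >= 1")
  p <- model$params
  probs_h <- c(1 - p[["p21"]] - p[["p31"]] - p[["p41"]],
               p[["p21"]], p[["p31"]], p[["p41"]])
  probs_i <- c(1 - p[["p12"]] - p[["p32"]] - p[["p42"]],
               p[["p12"]], p[["p32"]], p[["p42"]])
  w <- round(Q0 - model$initial_ill)
  x <- round(model$initial_ill)
  repl <- 0L
  cols <- c("year", "healthy_start", "ill_start",
            "healthy_to_ill", "healthy_to_death_other", "healthy_to_suicide",
            "ill_to_recovered", "ill_to_death_other", "ill_to_suicide",
            "replacements")
  m <- matrix(0, nrow = years, ncol = length(cols),
              dimnames = list(NULL, cols))
  for (yr in seq_len(years)) {
    eh <- stats::rmultinom(1, size = w, prob = probs_h)[, 1]
    ei <- stats::rmultinom(1, size = x, prob = probs_i)[, 1]
    m[yr, ] <- c(yr, w, x, eh[2], eh[3], eh[4], ei[2], ei[3], ei[4], repl)
    deaths <- eh[3] + eh[4] + ei[3] + ei[4]
    w <- eh[1] + ei[2] + deaths   # stayers + recovered + replaced newborns
    x <- eh[2] + ei[1]            # newly ill + still ill
    # replacement enters w immediately *for next year's start*: record it
    repl <- deaths
  }
  out <- as.data.frame(m)
  class(out) <- c("cohort_tallies", "data.frame")
  attr(out, "Q0") <- Q0
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else seed
  out
}

#' Re-estimate the transition probabilities from simulated tallies
#'
#' Pools the yearly transition tallies of a cohort simulation and
#' estimates each annual transition probability as total events of that
#' flow divided by total start-of-year count of the source compartment
#' (person-years at risk), with binomial standard errors
#' `sqrt(p(1-p)/exposure)`. This closes the analysis loop: parameters in,
#' stochastic data out, parameters recovered.
#'
#' @param tallies a `"cohort_tallies"` data frame from
#'   [simulate.suicide_model()].
#' @param burn_in number of initial years to discard before pooling
#'   (default 0; use ~50 when the run starts far from equilibrium and the
#'   goal is a stationary-state estimate — for probability recovery the
#'   transient years are fine, since the rates do not change over time).
#' @return An object of class `"transition_fit"`: a list with `estimates`
#'   (a [transition_params]-style named vector), `se`, `exposure`
#'   (person-years at risk per source compartment), `events` and
#'   `years_used`. Methods: `coef()`, `confint()`, `print()`.
#' @examples
#' m <- suicide_model(Q0 = 1e5, initial_ill = 2143)
#' fit <- estimate_transitions(simulate(m, seed = 7, years = 100))
#' coef(fit)
#' @export
estimate_transitions <- function(tallies, burn_in = 0) {
  stopifnot(inherits(tallies, "data.frame"))
  if (burn_in >= nrow(tallies))
    stop("burn_in leaves no years of tallies")
  t <- tallies[tallies$year > burn_in, , drop = FALSE]
  if (nrow(t) < 1) stop("at least 1 year of tallies required")
  exp_h <- sum(t$healthy_start)
  exp_i <- sum(t$ill_start)
  flows <- c(p21 = "healthy_to_ill", p12 = "ill_to_recovered",
             p31 = "healthy_to_death_other", p32 = "ill_to_death_other",
             p41 = "healthy_to_suicide", p42 = "ill_to_suicide")
  from_healthy <- c(p21 = TRUE, p12 = FALSE, p31 = TRUE, p32 = FALSE,
                    p41 = TRUE, p42 = FALSE)
  est <- se <- events <- stats::setNames(numeric(6), names(flows))
  for (nm in names(flows)) {
    expo <- if (from_healthy[[nm]]) exp_h else exp_i
    if (expo == 0)
      stop("zero exposure: no person-years at risk for ", nm,
           ", estimate undefined")
    k <- sum(t[[flows[[nm]]]])
    events[[nm]] <- k
    est[[nm]] <- k / expo
    se[[nm]] <- sqrt(est[[nm]] * (1 - est[[nm]]) / expo)
  }
  structure(list(
    estimates = validate_parameters(est),
    se = se, events = events,
    exposure = c(healthy = exp_h, ill = exp_i),
    years_used = nrow(t)),
    class = "transition_fit")
}

#' @export
coef.transition_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$estimates), names(object$estimates))
}

#' @export
confint.transition_fit <- function(object, parm = names(object$estimates),
                                   level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  est <- coef(object)[parm]
  ci <- cbind(lower = pmax(est - q * object$se[parm], 0),
              upper = pmin(est + q * object$se[parm], 1))
  rownames(ci) <- parm
  ci
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf(
    "Transition probabilities estimated from %d years of cohort tallies\n",
    x$years_used))
  cat(sprintf("  exposure: %.0f healthy and %.0f ill person-years\n",
              x$exposure[["healthy"]], x$exposure[["ill"]]))
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %-12s (events %.0f, SE %.2e)\n", nm,
                format(x$estimates[[nm]], digits = 5),
                x$events[[nm]], x$se[[nm]]))
  invisible(x)
}

#' Pearson residuals of simulated tallies against model probabilities
#'
#' For each simulated year and each of the six flows, the standardized
#' difference between the observed event count and its binomial
#' expectation under the given (or re-estimated) probabilities:
#' `(k - n p) / sqrt(n p (1 - p))`. Under a correctly specified model
#' these are approximately standard normal.
#'
#' @param object a `"cohort_tallies"` data frame.
#' @param params a [transition_params] to test against; defaults to the
#'   probabilities re-estimated from the tallies themselves.
#' @param ... unused.
#' @return A data frame of per-year Pearson residuals, one column per flow.
#' @export
residuals.cohort_tallies <- function(object, params = NULL, ...) {
  if (is.null(params)) params <- estimate_transitions(object)$estimates
  params <- validate_parameters(params)
  flows <- c(p21 = "healthy_to_ill", p12 = "ill_to_recovered",
             p31 = "healthy_to_death_other", p32 = "ill_to_death_other",
             p41 = "healthy_to_suicide", p42 = "ill_to_suicide")
  from_healthy <- c(p21 = TRUE, p12 = FALSE, p31 = TRUE, p32 = FALSE,
                    p41 = TRUE, p42 = FALSE)
  out <- data.frame(year = object$year)
  for (nm in names(flows)) {
    n <- if (from_healthy[[nm]]) object$healthy_start else object$ill_start
    p <- params[[nm]]
    v <- n * p * (1 - p)
    out[[flows[[nm]]]] <- ifelse(v > 0,
                                 (object[[flows[[nm]]]] - n * p) / sqrt(v),
                                 0)
  }
  out
}
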