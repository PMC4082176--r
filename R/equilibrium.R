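#' Closed-form stationary distribution of the replacement dynamics
#'
#' The yearly evolution map with death-replacement has a unique fixed point
#' up to normalization. Writing `S = p12 + p32 + p42` for the total exit
#' probability of the ill compartment, the unnormalized stationary vector is
#' \deqn{(w, x, y, z) \propto (S,\; p_{21},\; p_{31} S + p_{32} p_{21},\;
#'       p_{41} S + p_{42} p_{21})}
#' with normalizer
#' \deqn{R = (1 + p_{31} + p_{41})\, S + p_{21}\,(1 + p_{32} + p_{42}),}
#' so each compartment's stationary count is `Q0` times its entry divided
#' by `R`. The fractions sum to one by construction (the sum of the four
#' entries is exactly `R`).
#'
#' When `S = 0` the living ill state is absorbing and the printed formula
#' degenerates to the zero vector; this is an error (`"degenerate chain"`),
#' not a limit.
#'
#' @param model a `"suicide_model"` (or a [transition_params] object, in
#'   which case `Q0` must be given).
#' @param Q0 total population size; taken from the model if omitted.
#' @return An object of class `"suicide_equilibrium"`: a list with
#'   `fractions` (named `w, x, y, z`), `counts` (fractions times `Q0`),
#'   `R`, `Q0` and `rates` — the suicide rate per 100,000, the other-cause
#'   death rate per 1,000 and the mentally ill percentage.
#' @examples
#' eq <- equilibrium(suicide_model())
#' eq$rates
#' @export
equilibrium <- function(model, Q0 = NULL) {
  if (inherits(model, "suicide_model")) {
    params <- model$params
    if (is.null(Q0)) Q0 <- model$Q0
  } else {
    params <- validate_parameters(model)
    if (is.null(Q0)) stop("Q0 must be supplied with raw parameters")
  }
  p <- params
  S <- p[["p12"]] + p[["p32"]] + p[["p42"]]
  if (S <= 0)
    stop("degenerate chain: p12 + p32 + p42 = 0, the mentally ill state ",
         "is absorbing for the living and the stationary formula is ",
         "indeterminate")
  R <- (1 + p[["p31"]] + p[["p41"]]) * S +
    p[["p21"]] * (1 + p[["p32"]] + p[["p42"]])
  v <- c(w = S,
         x = p[["p21"]],
         y = p[["p31"]] * S + p[["p32"]] * p[["p21"]],
         z = p[["p41"]] * S + p[["p42"]] * p[["p21"]])
  fr <- v / R
  structure(list(
    fractions = fr,
    counts = fr * Q0,
    R = R,
    Q0 = Q0,
    params = params,
    rates = c(suicide_per_100k = 1e5 * fr[["z"]],
              other_death_per_1k = 1e3 * fr[["y"]],
              mentally_ill_pct = 100 * fr[["x"]])),
    class = "suicide_equilibrium")
}

#' @export
print.suicide_equilibrium <- function(x, digits = 3, ...) {
  cat("Stationary state of the replacement dynamics\n")
  cat(sprintf("  normalizer R = %s,  Q0 = %s\n",
              format(x$R, digits = 8), format(x$Q0, big.mark = ",")))
  lab <- c(w = "healthy           ", x = "mentally ill      ",
           y = "other-cause deaths", z = "suicides          ")
  for (nm in names(lab))
    cat(sprintf("  %s  fraction %-11s count/year %s\n", lab[[nm]],
                format(x$fractions[[nm]], digits = digits + 2),
                format(round(x$counts[[nm]]), big.mark = ",")))
  cat(sprintf(
    "  suicide rate %.1f per 100,000 | other-cause deaths %.2f per 1,000 | mentally ill %.1f%%\n",
    x$rates[["suicide_per_100k"]], x$rates[["other_death_per_1k"]],
    x$rates[["mentally_ill_pct"]]))
  invisible(x)
}
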