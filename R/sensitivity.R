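# Equilibrium suicide count z = Q0 * N / R with
#   S = p12 + p32 + p42,  N = p41*S + p42*p21,
#   R = (1 + p31 + p41)*S + p21*(1 + p32 + p42).
.zNR <- function(p, Q0) {
  S <- p[["p12"]] + p[["p32"]] + p[["p42"]]
  N <- p[["p41"]] * S + p[["p42"]] * p[["p21"]]
  R <- (1 + p[["p31"]] + p[["p41"]]) * S +
    p[["p21"]] * (1 + p[["p32"]] + p[["p42"]])
  list(S = S, N = N, R = R, z = Q0 * N / R)
}

.param_names <- c("p21", "p12", "p31", "p32", "p41", "p42")

# round half away from zero, the convention used for the published table
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Sensitivity of the equilibrium suicide count to one parameter
#'
#' Computes the partial derivative of the stationary annual suicide count
#' `z = Q0 * N / R` with respect to one of the six transition
#' probabilities, differentiating through the full dependence of
#' `N = p41*S + p42*p21`, `S = p12 + p32 + p42` and the normalizer `R` on
#' the perturbed parameter.
#'
#' Three methods are available. `"analytic"` (the canonical one) uses the
#' quotient rule on `N/R`. `"finite-difference"` uses central differences
#' with step `h` and exists as an independent numerical check.
#' `"approximate"` is the back-of-envelope shortcut that ignores the
#' response of the equilibrium itself and returns the source compartment's
#' stationary count (`w`-count for `p41`, `x`-count for `p42`): adequate at
#' the reference scenario but inconsistent with the published
#' equivalent-perturbation column, hence documented and not the default.
#'
#' @param model a `"suicide_model"` (or [transition_params] with `Q0`
#'   supplied).
#' @param which one of `"p21", "p12", "p31", "p32", "p41", "p42"`.
#' @param method `"analytic"`, `"finite-difference"` or `"approximate"`.
#' @param h central-difference step (default 1e-8).
#' @param Q0 population size; taken from the model if omitted.
#' @return The derivative, in suicides per year per unit probability.
#' @examples
#' m <- suicide_model()
#' dz_dparam(m, "p41") * 1e-5   # ~67.2 fewer suicides per 1e-5 reduction
#' dz_dparam(m, "p42") * 1e-5   # ~2.3
#' @export
dz_dparam <- function(model, which,
                      method = c("analytic", "finite-difference",
                                 "approximate"),
                      h = 1e-8, Q0 = NULL) {
  method <- match.arg(method)
  if (inherits(model, "suicide_model")) {
    p <- model$params
    if (is.null(Q0)) Q0 <- model$Q0
  } else {
    p <- validate_parameters(model)
    if (is.null(Q0)) stop("Q0 must be supplied with raw parameters")
  }
  if (!is.character(which) || length(which) != 1 ||
      !(which %in% .param_names))
    stop("unknown parameter name: ", paste(which, collapse = ", "))
  if (method == "finite-difference") {
    zp <- function(val) {
      q <- unclass(p); q[[which]] <- val
      .zNR(q, Q0)$z
    }
    return((zp(p[[which]] + h) - zp(p[[which]] - h)) / (2 * h))
  }
  g <- .zNR(p, Q0)
  if (method == "approximate") {
    frac <- switch(which,
                   p41 = g$S / g$R,        # stationary healthy fraction
                   p42 = p[["p21"]] / g$R, # stationary ill fraction
                   stop("approximate method is defined only for p41 and p42"))
    return(Q0 * frac)
  }
  # analytic: dz/dp = Q0 * (N' R - N R') / R^2, with S' folded into N', R'
  dN <- switch(which,
               p21 = p[["p42"]],
               p12 = p[["p41"]],
               p31 = 0,
               p32 = p[["p41"]],
               p41 = g$S,
               p42 = p[["p41"]] + p[["p21"]])
  dR <- switch(which,
               p21 = 1 + p[["p32"]] + p[["p42"]],
               p12 = 1 + p[["p31"]] + p[["p41"]],
               p31 = g$S,
               p32 = (1 + p[["p31"]] + p[["p41"]]) + p[["p21"]],
               p41 = g$S,
               p42 = (1 + p[["p31"]] + p[["p41"]]) + p[["p21"]])
  Q0 * (dN * g$R - g$N * dR) / g$R^2
}

#' First-order projection of an intervention's effect on suicides
#'
#' Linearizes the stationary suicide count around the current parameters:
#' a change of `dp` in parameter `which` changes the annual suicide count
#' by approximately `dp` times the analytic derivative. Interventions
#' *decrease* probabilities; the returned number is the projected
#' *reduction* in suicides per year for a decrease of `dp`.
#'
#' @inheritParams dz_dparam
#' @param dp size of the probability change (e.g. 1e-5 for 1 per 100,000).
#' @return Projected change in suicides per year.
#' @examples
#' m <- suicide_model()
#' project_delta_z(m, "p41", 1e-5)   # population-wide strategy
#' project_delta_z(m, "p42", 1e-5)   # high-risk strategy
#' @export
project_delta_z <- function(model, which, dp, Q0 = NULL) {
  dp * dz_dparam(model, which, method = "analytic", Q0 = Q0)
}

#' Equivalent high-risk perturbation matching a population-wide one
#'
#' How much must the mentally ill compartment's suicide probability `p42`
#' change to save as many suicides as a change of `reference_dp41` in the
#' whole healthy population's probability `p41`? The linearized answer
#' divides the projected reduction by the analytic derivative with respect
#' to `p42`; the exact answer root-finds (by bisection, tolerance 1e-12 in
#' the probability) the perturbation of `p42` whose recomputed equilibrium
#' changes the suicide count by the same amount. At the Hong Kong
#' reference this is about 29e-5 — roughly thirty times the reference
#' perturbation, the Rose-theorem differential.
#'
#' @inheritParams dz_dparam
#' @param reference_dp41 the reference perturbation of `p41` (> 0).
#' @param mode `"linearized"` or `"exact"`.
#' @return The equivalent perturbation of `p42`, as a probability.
#' @examples
#' equivalent_delta_p42(suicide_model()) / 1e-5   # ~29
#' @export
equivalent_delta_p42 <- function(model, reference_dp41 = 1e-5,
                                 mode = c("linearized", "exact"),
                                 Q0 = NULL) {
  mode <- match.arg(mode)
  if (inherits(model, "suicide_model")) {
    p <- model$params
    if (is.null(Q0)) Q0 <- model$Q0
  } else {
    p <- validate_parameters(model)
    if (is.null(Q0)) stop("Q0 must be supplied with raw parameters")
  }
  if (!is.numeric(reference_dp41) || reference_dp41 <= 0)
    stop("reference_dp41 must be > 0")
  target_dz <- reference_dp41 * dz_dparam(p, "p41", Q0 = Q0)
  if (mode == "linearized")
    return(target_dz / dz_dparam(p, "p42", Q0 = Q0))
  # exact: bisection for the d with z(p42 + d) - z(p42) = target_dz,
  # d in [0, 1 - p12 - p32 - p42] (the room left in the ill row)
  z0 <- .zNR(p, Q0)$z
  f <- function(d) {
    q <- unclass(p); q[["p42"]] <- q[["p42"]] + d
    .zNR(q, Q0)$z - z0 - target_dz
  }
  lo <- 0
  hi <- 1 - (p[["p12"]] + p[["p32"]] + p[["p42"]])
  if (f(lo) > 0 || f(hi) < 0)
    stop("required suicide-count change is unreachable by perturbing p42 ",
         "within [0, ", format(hi), "]")
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Full sensitivity report of the equilibrium suicide count
#'
#' Evaluates the analytic derivative of the stationary suicide count with
#' respect to each of the six transition probabilities, the first-order
#' projected reduction for a reference decrease of `p41` by `dp`, its
#' relative size, and the equivalent perturbation of `p42`.
#'
#' @param model a `"suicide_model"`.
#' @param dp reference perturbation of `p41` (default 1e-5).
#' @return An object of class `"suicide_sensitivity"`: a list with
#'   `z_count`, `dz_dp` (named vector over the six parameters), `dp`,
#'   `delta_z`, `delta_z_over_z` and `equivalent_dp42`.
#' @examples
#' sensitivity(suicide_model())
#' @export
sensitivity <- function(model, dp = 1e-5) {
  stopifnot(inherits(model, "suicide_model"))
  dz <- vapply(.param_names, function(nm) dz_dparam(model, nm),
               numeric(1))
  z <- .zNR(model$params, model$Q0)$z
  delta_z <- dp * dz[["p41"]]
  structure(list(
    params = model$params, Q0 = model$Q0,
    z_count = z, dz_dp = dz, dp = dp,
    delta_z = delta_z,
    delta_z_over_z = delta_z / z,
    equivalent_dp42 = delta_z / dz[["p42"]]),
    class = "suicide_sensitivity")
}

#' @export
print.suicide_sensitivity <- function(x, ...) {
  cat("Sensitivity of the stationary suicide count\n")
  cat(sprintf("  suicides/year at equilibrium: %.1f (Q0 = %s)\n",
              x$z_count, format(x$Q0, big.mark = ",")))
  cat("  dz/dp (suicides per unit probability):\n")
  for (nm in names(x$dz_dp))
    cat(sprintf("    %s: %s\n", nm, format(x$dz_dp[[nm]], digits = 6)))
  cat(sprintf(
    "  reducing p41 by %g: %.1f fewer suicides/year (%.1f%% of all suicides)\n",
    x$dp, x$delta_z, 100 * x$delta_z_over_z))
  cat(sprintf(
    "  reducing p42 by %g: %.1f fewer suicides/year\n",
    x$dp, x$dp * x$dz_dp[["p42"]]))
  cat(sprintf(
    "  equivalent p42 change for the same effect: %.1fe-5 (%.1f times larger)\n",
    x$equivalent_dp42 / 1e-5, x$equivalent_dp42 / x$dp))
  invisible(x)
}

# (p41, p42) combinations of the published sensitivity sweep, in four
# blocks: reference (the model's own suicide probabilities); p42 fixed;
# p41 fixed; ratio p42/p41 fixed at 30
.scenario_grid <- function(p41_ref = 0.0000834, p42_ref = 0.0025) {
  rbind(
    data.frame(block = "reference", p41 = p41_ref, p42 = p42_ref),
    data.frame(block = "p42 fixed",
               p41 = c(0.00001, 0.0001, 0.0005), p42 = 0.0025),
    data.frame(block = "p41 fixed", p41 = 0.0000834,
               p42 = c(0.0001, 0.001, 0.005, 0.01)),
    data.frame(block = "ratio fixed",
               p41 = c(0.00001, 0.0001, 0.0005),
               p42 = c(0.0003, 0.003, 0.015)))
}

#' Scenario sweep over the suicide probabilities of both compartments
#'
#' Recomputes the stationary suicide count, the projected reduction from a
#' reference decrease of `p41`, its relative size and the equivalent `p42`
#' perturbation over an 11-scenario grid of `(p41, p42)` pairs — the
#' reference conditions, three scenarios with `p42` fixed, four with `p41`
#' fixed and three holding the ratio `p42/p41` at 30 — with all other
#' parameters held at the model's values. The projected reduction is
#' nearly invariant (about 67 suicides/year for a 1-per-100,000 decrease
#' of `p41`) because it is dominated by the healthy fraction, while the
#' equivalent high-risk perturbation stays about thirty times larger:
#' the Rose prevention paradox in table form.
#'
#' @param model a `"suicide_model"`; its `p21, p12, p31, p32` are held
#'   fixed across rows.
#' @param reference_dp41 reference decrease of `p41` (default 1e-5).
#' @return A data frame of class `c("sensitivity_table", "data.frame")`
#'   with columns `block, p41, p42, ratio, z, delta_z, delta_z_pct,
#'   equiv_dp42_1e5`. `z` and `delta_z` are rounded to integers,
#'   `delta_z_pct` to one decimal and `equiv_dp42_1e5` to the nearest
#'   integer in units of 1e-5, all half-away-from-zero; the unrounded
#'   values are kept in columns prefixed `raw_`.
#' @examples
#' sensitivity_table(suicide_model())
#' @export
sensitivity_table <- function(model, reference_dp41 = 1e-5) {
  stopifnot(inherits(model, "suicide_model"))
  grid <- .scenario_grid(model$params[["p41"]], model$params[["p42"]])
  base <- unclass(model$params)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    q <- base
    q[["p41"]] <- grid$p41[i]
    q[["p42"]] <- grid$p42[i]
    q <- validate_parameters(q)
    z <- .zNR(q, model$Q0)$z
    dz <- reference_dp41 * dz_dparam(q, "p41", Q0 = model$Q0)
    eq42 <- dz / dz_dparam(q, "p42", Q0 = model$Q0)
    data.frame(
      block = grid$block[i],
      p41 = grid$p41[i], p42 = grid$p42[i],
      ratio = grid$p42[i] / grid$p41[i],
      z = round_half_up(z), delta_z = round_half_up(dz),
      delta_z_pct = round_half_up(100 * dz / z, 1),
      equiv_dp42_1e5 = round_half_up(eq42 / 1e-5),
      raw_z = z, raw_delta_z = dz, raw_equiv_dp42 = eq42)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_table", "data.frame")
  attr(out, "reference_dp41") <- reference_dp41
  out
}

#' @export
print.sensitivity_table <- function(x, ...) {
  need <- c("block", "p41", "p42", "ratio", "z", "delta_z",
            "delta_z_pct", "equiv_dp42_1e5")
  if (!all(need %in% names(x))) return(NextMethod())
  cat(sprintf(
    "Sensitivity of the suicide count to p41 and p42 (reference dp41 = %g)\n",
    attr(x, "reference_dp41")))
  df <- data.frame(block = x$block, p41 = x$p41, p42 = x$p42,
                   `p42/p41` = round_half_up(x$ratio), z = x$z,
                   dz = x$delta_z,
                   `dz/z` = sprintf("%.1f%%", x$delta_z_pct),
                   `dp42 (1e-5)` = x$equiv_dp42_1e5,
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
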