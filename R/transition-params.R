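#' Annual transition probabilities of the illness-death model
#'
#' Constructs and validates the six one-year transition probabilities of the
#' four-state suicide dynamics model. States are numbered 1 = healthy,
#' 2 = mentally ill, 3 = death from causes other than suicide, 4 = death by
#' suicide; `p_ij` is the annual probability of moving *to* state `i` *from*
#' state `j`.
#'
#' The defaults are the Hong Kong 2012 estimates: an annual psychiatric
#' incidence of 0.286% among the healthy, a recovery rate of 6.67% among the
#' mentally ill, other-cause death rates of 6 per 1,000 (healthy) and 12 per
#' 1,000 (ill), and suicide rates of 8.34 per 100,000 (healthy) and 250 per
#' 100,000 (ill).
#'
#' @param p21 probability/year that a healthy person is diagnosed mentally ill.
#' @param p12 probability/year that a mentally ill person recovers.
#' @param p31 probability/year that a healthy person dies of other causes.
#' @param p32 probability/year that a mentally ill person dies of other causes.
#' @param p41 probability/year that a healthy person dies by suicide.
#' @param p42 probability/year that a mentally ill person dies by suicide.
#'
#' @return A named numeric vector of class `"transition_params"` with
#'   elements `p21, p12, p31, p32, p41, p42`.
#'
#' @details Each probability must lie in `[0, 1]`, and the exit probabilities
#'   of each living compartment must not exceed 1:
#'   `p21 + p31 + p41 <= 1` (healthy row) and `p12 + p32 + p42 <= 1`
#'   (mentally ill row). Violations are errors, not warnings.
#'
#' @examples
#' transition_params()                    # Hong Kong defaults
#' transition_params(p42 = 0.01)          # stronger excess risk when ill
#' @export
transition_params <- function(p21 = 0.00286, p12 = 0.0667,
                              p31 = 0.006, p32 = 0.012,
                              p41 = 0.0000834, p42 = 0.0025) {
  p <- c(p21 = p21, p12 = p12, p31 = p31, p32 = p32, p41 = p41, p42 = p42)
  validate_parameters(structure(p, class = "transition_params"))
}

#' Validate a set of transition probabilities
#'
#' Checks the probabilistic invariants of a [transition_params] object and
#' returns it unchanged if they hold.
#'
#' @param params a `"transition_params"` object or a named numeric vector
#'   with elements `p21, p12, p31, p32, p41, p42`.
#' @return `params`, invisibly unchanged, as a `"transition_params"` object.
#' @export
validate_parameters <- function(params) {
  nm <- c("p21", "p12", "p31", "p32", "p41", "p42")
  if (!is.numeric(params) || !all(nm %in% names(params)))
    stop("params must be numeric with elements ", paste(nm, collapse = ", "))
  p <- unclass(params)[nm]
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    bad <- nm[!is.finite(p) | p < 0 | p > 1]
    stop("invalid probability: ", paste(bad, collapse = ", "),
         " must lie in [0, 1]")
  }
  healthy_exit <- p[["p21"]] + p[["p31"]] + p[["p41"]]
  ill_exit     <- p[["p12"]] + p[["p32"]] + p[["p42"]]
  if (healthy_exit > 1 + 1e-12)
    stop("row overflow: healthy-state exits p21 + p31 + p41 = ",
         format(healthy_exit), " exceed 1")
  if (ill_exit > 1 + 1e-12)
    stop("row overflow: mentally-ill-state exits p12 + p32 + p42 = ",
         format(ill_exit), " exceed 1")
  structure(p, class = "transition_params")
}

#' @export
print.transition_params <- function(x, digits = 6, ...) {
  cat("Annual transition probabilities (illness-death model)\n")
  lab <- c(p21 = "healthy -> mentally ill  ",
           p12 = "ill -> recovered         ",
           p31 = "healthy -> death (other) ",
           p32 = "ill -> death (other)     ",
           p41 = "healthy -> suicide       ",
           p42 = "ill -> suicide           ")
  for (nm in names(lab))
    cat(sprintf("  %s %s  %s\n", nm, lab[[nm]],
                format(x[[nm]], digits = digits)))
  invisible(x)
}

# exit-row sums used throughout: S drives the ill compartment's turnover
.row_sums <- function(p) {
  list(S = p[["p12"]] + p[["p32"]] + p[["p42"]],
       healthy_exit = p[["p21"]] + p[["p31"]] + p[["p41"]])
}
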