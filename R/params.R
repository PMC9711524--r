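#' Kinetic parameter set of the IacR--MarR dual-feedback circuit
#'
#' Bundles every rate constant of the two-variable activator--repressor
#' model.  IacR (transcriptional activator) activates its own production
#' and that of MarR (transcriptional repressor); MarR widens the Hill
#' denominator of IacR production.  The phytohormones act on turnover:
#' auxin (IAA) multiplies IacR turnover by `1 + eps_I * IAA(t)`,
#' salicylate (SA) multiplies MarR turnover by `1 + eps_M * SA(t)`.
#'
#' @param a1,a2 basal production rates of IacR and MarR
#'   (concentration/hour).
#' @param b1,b2 IacR-dependent (auto/cross-activated) production rates
#'   (concentration/hour).
#' @param K_A,K_B half-maximal Hill coefficients (concentration units);
#'   must be strictly positive.
#' @param gamma dimensionless scaling of MarR inside the IacR Hill
#'   denominator (strength of MarR-dependent repression).
#' @param d1,d2 first-order protein turnover rates (1/hour); strictly
#'   positive so that a rest state exists.
#' @param eps_I,eps_M hormone effect rates on turnover
#'   (1/stimulus-unit).
#'
#' @return An object of class `circuit_params` (a named list of the
#'   eleven rate constants).
#' @seealso [default_circuit_params()] for the calibrated excitable set.
#' @export
circuit_params <- function(a1, a2, b1, b2, K_A, K_B, gamma,
                           d1, d2, eps_I = 0, eps_M = 0) {
  p <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, K_A = K_A, K_B = K_B,
            gamma = gamma, d1 = d1, d2 = d2, eps_I = eps_I, eps_M = eps_M)
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

validate_circuit_params <- function(p) {
  nm <- c("a1", "a2", "b1", "b2", "K_A", "K_B", "gamma",
          "d1", "d2", "eps_I", "eps_M")
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("circuit_params: missing fields: ", paste(missing, collapse = ", "))
  vals <- unlist(p[nm])
  if (!all(is.finite(vals)))
    stop("circuit_params: all fields must be finite numbers")
  if (any(vals < 0))
    stop("circuit_params: all fields must be >= 0 (got negative ",
         paste(nm[vals < 0], collapse = ", "), ")")
  if (p$d1 <= 0 || p$d2 <= 0)
    stop("circuit_params: turnover rates d1 and d2 must be strictly positive")
  if (p$K_A <= 0 || p$K_B <= 0)
    stop("circuit_params: Hill coefficients K_A and K_B must be strictly positive")
  invisible(p)
}

#' Calibrated default parameter set (excitable regime)
#'
#' The reference parameter set used throughout the package.  It was
#' calibrated by the documented procedure: fix `a1 = a2`, `b1 = b2`,
#' `K_A = K_B`, `gamma`, `eps_I = eps_M`, then scan the turnover ratio
#' `d1/d2` until (i) the unforced system is excitable (single stable
#' rest state, large transient excursion after a super-threshold kick),
#' (ii) varying `d1/d2` alone traverses steady, excitable and
#' oscillatory regimes, and (iii) antithetic square-wave forcing with
#' periods between 30 minutes and 3 hours entrains the response 1:1.
#'
#' @return A `circuit_params` object.
#' @export
default_circuit_params <- function() {
  circuit_params(
    a1 = 0.4,   a2 = 0.015,
    b1 = 60,    b2 = 1.5,
    K_A = 0.3,  K_B = 3,
    gamma = 9.54,
    d1 = 3,     d2 = 0.08,
    eps_I = 5,  eps_M = 80
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  cat(sprintf("  production : a1=%g a2=%g b1=%g b2=%g\n",
              x$a1, x$a2, x$b1, x$b2))
  cat(sprintf("  Hill       : K_A=%g K_B=%g gamma=%g\n",
              x$K_A, x$K_B, x$gamma))
  cat(sprintf("  turnover   : d1=%g d2=%g (d1/d2=%g)\n",
              x$d1, x$d2, x$d1 / x$d2))
  cat(sprintf("  hormones   : eps_I=%g eps_M=%g\n", x$eps_I, x$eps_M))
  invisible(x)
}
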