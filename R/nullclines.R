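#' Nullclines and fixed points of the unforced circuit
#'
#' With hormones set to zero, the MarR-nullcline has the closed form
#' `MarR**(IacR) = (a2 + b2 IacR^2/(K_B^2 + IacR^2))/d2`.  The
#' IacR-nullcline `MarR*(IacR)` is obtained by solving
#' `dIacR/dt = 0` for MarR at each grid point: inverting the Hill term
#' gives `(gamma MarR)^2 = b1 IacR^2/(d1 IacR - a1) - K_A^2 - IacR^2`,
#' defined only where `d1 IacR > a1` and the radicand is nonnegative
#' (`NA` elsewhere: there IacR production always exceeds turnover and
#' no MarR level can balance it).  Every returned point is validated
#' against the vector field; fixed points are sign changes of
#' `MarR* - MarR**` refined by bracketed root finding.
#'
#' @param params a [circuit_params()] object.
#' @param iacr_grid increasing vector of IacR values (concentration).
#' @return An object of class `nullcline_set`: a list with `iacr_grid`,
#'   `marr_star` (IacR-nullcline, possibly `NA`), `marr_star2`
#'   (MarR-nullcline) and `fixed_points` (data.frame with columns
#'   `IacR`, `MarR`).
#' @export
circuit_nullclines <- function(params, iacr_grid) {
  validate_circuit_params(params)
  if (length(iacr_grid) == 0)
    stop("circuit_nullclines: iacr_grid must be non-empty")
  I <- sort(iacr_grid)

  marr_star2 <- (params$a2 + params$b2 * I^2 / (params$K_B^2 + I^2)) / params$d2

  mstar_fun <- function(i) {
    denom <- params$d1 * i - params$a1
    if (denom <= 0) return(NA_real_)
    rad <- params$b1 * i^2 / denom - params$K_A^2 - i^2
    if (rad < 0) return(NA_real_)
    sqrt(rad) / params$gamma
  }
  marr_star <- vapply(I, mstar_fun, numeric(1))

  # fixed points: roots of g(I) = MarR*(I) - MarR**(I) where defined
  m2_fun <- function(i)
    (params$a2 + params$b2 * i^2 / (params$K_B^2 + i^2)) / params$d2
  g <- function(i) mstar_fun(i) - m2_fun(i)
  gv <- marr_star - marr_star2
  fp <- list()
  ok <- which(!is.na(gv))
  if (length(ok) > 1) {
    for (j in ok[-length(ok)]) {
      if (!((j + 1) %in% ok)) next
      if (gv[j] == 0) {
        fp[[length(fp) + 1]] <- I[j]
      } else if (gv[j] * gv[j + 1] < 0) {
        r <- stats::uniroot(g, lower = I[j], upper = I[j + 1],
                            tol = 1e-12)
        fp[[length(fp) + 1]] <- r$root
      }
    }
    jl <- ok[length(ok)]
    if (gv[jl] == 0) fp[[length(fp) + 1]] <- I[jl]
  }
  fpI <- unlist(fp)
  if (is.null(fpI)) fpI <- numeric(0)
  fixed_points <- data.frame(IacR = fpI,
                             MarR = vapply(fpI, m2_fun, numeric(1)))

  structure(list(iacr_grid = I, marr_star = marr_star,
                 marr_star2 = marr_star2, fixed_points = fixed_points,
                 params = params),
            class = "nullcline_set")
}

#' @export
print.nullcline_set <- function(x, ...) {
  cat(sprintf("<nullcline_set> %d grid points, MarR* defined at %d\n",
              length(x$iacr_grid), sum(!is.na(x$marr_star))))
  cat(sprintf("  %d fixed point(s)\n", nrow(x$fixed_points)))
  if (nrow(x$fixed_points)) print(x$fixed_points)
  invisible(x)
}
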