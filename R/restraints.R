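#' Wall restraint on a collective variable
#'
#' A one-sided polynomial wall of the kind metadynamics engines apply to
#' collective variables: zero on the allowed side and
#' `k * violation^exponent` beyond the limit, with no 1/2 prefactor
#' (matching the convention of the engine the published force constants come
#' from). A lower wall penalizes values below the limit, an upper wall
#' values above it.
#'
#' @param cv_name name of the restrained collective variable (e.g. "d1").
#' @param limit wall position, nm.
#' @param k force constant, kJ mol^-1 nm^-exponent; must be >= 0.
#' @param side "lower" or "upper".
#' @param exponent even integer >= 2.
#' @return An object of class `wall_restraint`.
#' @examples
#' w <- wall_restraint("d1", 2.4, 1500)
#' wall_energy(2.3, w) # 15 kJ/mol
#' @export
wall_restraint <- function(cv_name, limit, k = 1500,
                           side = c("lower", "upper"), exponent = 2L) {
  side <- match.arg(side)
  if (!is.finite(k) || k < 0) stop("invalid restraint: k must be >= 0")
  if (!is.finite(limit)) stop("invalid restraint: non-finite limit")
  exponent <- as.integer(exponent)
  if (exponent < 2L || exponent %% 2L != 0L)
    stop("invalid restraint: exponent must be an even integer >= 2")
  structure(list(cv_name = cv_name, limit = limit, k = k, side = side,
                 exponent = exponent),
            class = "wall_restraint")
}

#' Wall restraint energy
#'
#' @param value collective-variable value(s), nm.
#' @param restraint a [wall_restraint()].
#' @return Energy in kJ/mol, vectorized over `value`.
#' @export
wall_energy <- function(value, restraint) {
  stopifnot(inherits(restraint, "wall_restraint"))
  if (any(!is.finite(value))) stop("non-finite collective-variable value")
  viol <- if (restraint$side == "lower") restraint$limit - value
          else value - restraint$limit
  restraint$k * pmax(viol, 0)^restraint$exponent
}

#' @export
print.wall_restraint <- function(x, ...) {
  cat(sprintf("%s wall on %s at %g nm (k = %g kJ mol^-1 nm^-%d)\n",
              x$side, x$cv_name, x$limit, x$k, x$exponent))
  invisible(x)
}
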