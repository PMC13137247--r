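#' Synthetic trajectory fixture specification
#'
#' Declares one of the closed-form generators used to exercise the analysis
#' machinery on data whose answer is known exactly:
#' \describe{
#'   \item{two_state_torsion}{i.i.d. Psi torsions from the two-state
#'     Boltzmann distribution with gauche degeneracy 2 and a given gap.}
#'   \item{double_well_cv}{i.i.d. CV samples from the Boltzmann density of
#'     the quartic double well (inverse-CDF on a fine grid).}
#'   \item{bound_unbound_mixture}{a two-basin d_COM distribution with a
#'     prescribed bound/unbound free-energy difference.}
#' }
#'
#' @param generator one of the three generator names.
#' @param n number of frames.
#' @param seed mandatory RNG seed.
#' @param params named list of distribution parameters (see
#'   [generate_fixture()]).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(generator = c("two_state_torsion", "double_well_cv",
                                       "bound_unbound_mixture"),
                         n, seed, params = list()) {
  generator <- match.arg(generator)
  if (missing(seed) || is.null(seed)) stop("fixture seed is mandatory")
  stopifnot(n >= 1)
  structure(list(generator = generator, n = as.integer(n),
                 seed = as.integer(seed), params = params),
            class = "fixture_spec")
}

#' Generate a synthetic CV trajectory from a fixture specification
#'
#' All generators are seeded and exactly reproducible. Parameters by
#' generator (with defaults):
#' \describe{
#'   \item{two_state_torsion}{`gt_gap` (-4.09 kJ/mol), `temperature`
#'     (303.15 K), `n_torsions` (4), `jitter` (degrees of Gaussian spread
#'     around the state angles, default 8). Frames carry `psi*` columns.}
#'   \item{double_well_cv}{`height` (12 kJ/mol), `s0` (1), `temperature`
#'     (300 K). Frames carry an `s` column.}
#'   \item{bound_unbound_mixture}{`delta_f` (bound minus unbound, kJ/mol,
#'     default -5.48), `temperature` (300 K), `threshold` (3 nm). The
#'     bound basin is uniform on (1, threshold - 0.1), the unbound basin
#'     uniform on (threshold + 0.1, 6). The prescribed `delta_f` is stored
#'     in the trajectory's metadata.}
#' }
#'
#' @param spec a [fixture_spec()].
#' @return A [cv_trajectory()].
#' @examples
#' tr <- generate_fixture(fixture_spec("bound_unbound_mixture", 1000, seed = 7))
#' attr(tr, "delta_f")
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$params
  with_seed(spec$seed, switch(
    spec$generator,
    two_state_torsion = {
      gap <- p$gt_gap %||% -4.09
      temp <- p$temperature %||% 303.15
      nt <- p$n_torsions %||% 4
      jit <- p$jitter %||% 8
      bf <- 2 * exp(-gap / kBT(temp))       # gauche:trans odds, degeneracy 2
      p_g <- bf / (1 + bf)
      draw <- function(n) {
        state <- ifelse(runif(n) < p_g, sample(c(-70, 70), n, replace = TRUE),
                        180)
        normalize_angle(state + rnorm(n, 0, jit))
      }
      df <- data.frame(time = seq_len(spec$n))
      for (k in seq_len(nt)) df[[paste0("psi", k)]] <- draw(spec$n)
      cv_trajectory(df, temperature = temp, system = "fixture",
                    seed = spec$seed,
                    extra = list(gt_gap = gap, p_gauche = p_g),
                    subclass = "torsion_trajectory")
    },
    double_well_cv = {
      h <- p$height %||% 12
      s0 <- p$s0 %||% 1
      temp <- p$temperature %||% 300
      sys <- double_well_system(height = h, s0 = s0)
      grid <- seq(-2.5 * s0, 2.5 * s0, length.out = 4096)
      dens <- exp(-analytic_potential(sys, grid) / kBT(temp))
      cdf <- cumsum(dens) / sum(dens)
      s <- grid[findInterval(runif(spec$n), cdf) + 1]
      cv_trajectory(data.frame(time = seq_len(spec$n), s = s),
                    temperature = temp, system = "fixture", seed = spec$seed,
                    extra = list(height = h, s0 = s0))
    },
    bound_unbound_mixture = {
      dF <- p$delta_f %||% -5.48
      temp <- p$temperature %||% 300
      thr <- p$threshold %||% 3
      p_b <- 1 / (1 + exp(dF / kBT(temp))) # dF = -kT log(p_b / p_u)
      bnd <- runif(spec$n) < p_b
      d <- ifelse(bnd, runif(spec$n, 1, thr - 0.1),
                  runif(spec$n, thr + 0.1, 6))
      cv_trajectory(data.frame(time = seq_len(spec$n), d_COM = d),
                    temperature = temp, system = "fixture", seed = spec$seed,
                    extra = list(delta_f = dF, p_bound = p_b, threshold = thr))
    }))
}
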