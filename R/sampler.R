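#' Sample the coarse-grained chain by torsion-space Monte Carlo
#'
#' Metropolis Monte Carlo over the chain's Psi torsions (pivot moves: one
#' torsion is redrawn uniformly on the circle per attempt, rotating the
#' downstream arm rigidly; one sweep attempts every torsion once). The
#' energy is the torsion potential (scaled by `lambda` for solute-tempering
#' replicas), plus the wall restraint on d1 and any metadynamics bias, both
#' unscaled. Uniform proposals make the move set ergodic regardless of
#' barrier height; an acceptance watchdog still signals failure if the chain
#' stops moving entirely.
#'
#' @param geometry a [chain_geometry()].
#' @param potential a [torsion_potential()].
#' @param restraint optional [wall_restraint()] on d1.
#' @param temperature K.
#' @param n_sweeps number of MC sweeps (>= 1).
#' @param seed RNG seed; every source of randomness in the run flows from it.
#' @param bias optional [metad_bias()] on d1 acting during sampling.
#' @param deposit if `TRUE` and `bias` is given, deposit well-tempered
#'   Gaussians every `bias$pace` sweeps (the deposited history is returned in
#'   the `bias` attribute of the trajectory).
#' @param lambda Hamiltonian scaling of the torsion term, in (0, 1].
#' @param thin record every `thin`-th sweep.
#' @param psi0 starting torsions (degrees); default all-trans.
#' @param burnin fraction of initial frames dropped from the returned
#'   trajectory (0 keeps everything).
#' @return A `torsion_trajectory` (also a `cv_trajectory` data frame) with
#'   columns `time` (sweeps), `psi1..psiN` (degrees), `d1` (nm) and, when a
#'   bias is active, `metad.bias` (kJ/mol, the bias energy at the frame).
#'   Metadata (temperature, seed, restraint, lambda, acceptance, final bias)
#'   is stored in attributes.
#' @examples
#' g <- chain_geometry()
#' pot <- torsion_potential()
#' traj <- sample_chain(g, pot, wall_restraint("d1", 2.4, 1500),
#'                      n_sweeps = 2000, seed = 1)
#' gt_ratio(traj)
#' @export
sample_chain <- function(geometry, potential, restraint = NULL,
                         temperature = 300, n_sweeps, seed = NULL,
                         bias = NULL, deposit = FALSE, lambda = 1,
                         thin = 1L, psi0 = NULL, burnin = 0) {
  stopifnot(inherits(geometry, "chain_geometry"),
            inherits(potential, "torsion_potential"),
            n_sweeps >= 1, temperature > 0, lambda > 0, lambda <= 1,
            burnin >= 0, burnin < 1)
  if (!is.null(restraint)) stopifnot(inherits(restraint, "wall_restraint"))
  if (!is.null(bias)) stopifnot(inherits(bias, "metad_bias"))
  if (is.null(psi0)) psi0 <- rep(180, geometry$n_torsions)
  psi0 <- normalize_angle(psi0)

  span <- geometry$n_units * geometry$all_trans_repeat_length
  res <- with_seed(seed, chain_mc_cpp(
    psi0 = psi0, n_sweeps = as.integer(n_sweeps), thin = as.integer(thin),
    ell = geometry$bond_length, thetas = geometry$bond_angles,
    tors_bonds = geometry$torsion_bonds, n_beads = geometry$n_beads,
    term_a = geometry$terminal_beads$a, term_b = geometry$terminal_beads$b,
    coefs = potential$coefs, lambda = lambda,
    wall_on = !is.null(restraint),
    wall_limit = if (is.null(restraint)) 0 else restraint$limit,
    wall_k = if (is.null(restraint)) 0 else restraint$k,
    wall_side = if (!is.null(restraint) && restraint$side == "upper") -1L else 1L,
    wall_exp = if (is.null(restraint)) 2L else restraint$exponent,
    metad_on = !is.null(bias), metad_deposit = isTRUE(deposit),
    centers0 = if (is.null(bias)) numeric(0) else bias$centers[, 1],
    heights0 = if (is.null(bias)) numeric(0) else bias$heights,
    msigma = if (is.null(bias)) 0.05 else bias$sigma,
    mgamma = if (is.null(bias)) 15 else bias$gamma,
    mw0 = if (is.null(bias)) 0.5 else bias$w0,
    mpace = if (is.null(bias)) 0L else as.integer(bias$pace),
    gmin = 0, gmax = span * 1.25, ngrid = 2048L,
    temperature = temperature))

  if (n_sweeps >= 1000 && is.finite(res$acceptance) && res$acceptance < 1e-3)
    stop("sampler failure: acceptance rate stuck at ",
         signif(res$acceptance, 3))

  nt <- geometry$n_torsions
  out <- data.frame(time = seq_len(nrow(res$psi)) * thin)
  psi_cols <- paste0("psi", seq_len(nt))
  out[psi_cols] <- as.data.frame(res$psi)
  out$d1 <- res$d1
  if (!is.null(bias)) out[["metad.bias"]] <- res$bias
  if (burnin > 0) out <- out[-seq_len(floor(nrow(out) * burnin)), , drop = FALSE]
  rownames(out) <- NULL

  final_bias <- if (is.null(bias)) NULL else
    metad_bias_from_kernels(res$centers, res$heights, bias)
  cv_trajectory(out, temperature = temperature, lambda = lambda,
                system = "cg_chain", seed = seed,
                extra = list(restraint = restraint, acceptance = res$acceptance,
                             bias = final_bias, psi_final = res$psi_final,
                             potential = potential),
                subclass = "torsion_trajectory")
}

#' Gauche/trans population fractions of a torsion trajectory
#'
#' Counts every Psi torsion in every frame with the +/-120-degree
#' classification rule and returns the two fractions (which sum to 1).
#'
#' @param traj a `torsion_trajectory` from [sample_chain()], or a numeric
#'   vector/matrix of Psi angles in degrees.
#' @return Named numeric vector `c(gauche = ..., trans = ...)`.
#' @export
gt_ratio <- function(traj) {
  psi <- if (is.data.frame(traj)) {
    cols <- grep("^psi[0-9]+$", names(traj), value = TRUE)
    if (length(cols) == 0) stop("no psi columns in trajectory")
    as.matrix(traj[cols])
  } else as.matrix(traj)
  if (length(psi) == 0) stop("no data: empty trajectory")
  g <- mean(classify_torsion(as.numeric(psi)) == "gauche")
  c(gauche = g, trans = 1 - g)
}

#' Scan the gauche/trans equilibrium over lower-wall positions
#'
#' Reproduces the terminal-distance scan: for each d1 wall position the
#' chain is sampled with a lower wall (k = 1500 kJ mol^-1 nm^-2 by default)
#' and the gauche/trans fractions are recorded. Walls near the taut length
#' force the fully trans crystalline state; looser walls recover the
#' amorphous gauche-rich equilibrium.
#'
#' @param geometry,potential,temperature,n_sweeps,seed as [sample_chain()].
#' @param d1_values non-empty numeric vector of lower-wall positions, nm.
#'   A value of 0 (or a negative value) means unrestrained.
#' @param k wall force constant.
#' @param burnin fraction of frames dropped before counting.
#' @return Data frame with columns `d1_limit`, `gauche`, `trans`.
#' @export
scan_d1 <- function(geometry, potential, d1_values, temperature = 300,
                    n_sweeps = 20000, seed = 1, k = 1500, burnin = 0.2) {
  if (length(d1_values) == 0) stop("d1_values must be non-empty")
  rows <- lapply(seq_along(d1_values), function(i) {
    lim <- d1_values[i]
    res <- if (lim > 0) wall_restraint("d1", lim, k) else NULL
    traj <- sample_chain(geometry, potential, res, temperature = temperature,
                         n_sweeps = n_sweeps, seed = seed + i,
                         burnin = burnin)
    r <- gt_ratio(traj)
    data.frame(d1_limit = lim, gauche = r[["gauche"]], trans = r[["trans"]])
  })
  do.call(rbind, rows)
}
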