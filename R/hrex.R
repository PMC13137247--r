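#' Geometric lambda ladder for solute tempering
#'
#' The Hamiltonian-scaling ladder of a solute-tempering replica-exchange
#' setup: `lambda_i = lambda_min^((i-1)/(n-1))`, a geometric progression
#' from exactly 1 down to exactly `lambda_min`. With `n = 8` and
#' `lambda_min = 0.426934` this reproduces the eight published values
#' (1, 0.885511, 0.784132, 0.694357, 0.614861, 0.544467, 0.482133,
#' 0.426934).
#'
#' @param n number of replicas (>= 2).
#' @param lambda_min smallest scaling factor, in (0, 1).
#' @return A numeric vector of class `replica_ladder`, strictly decreasing
#'   from 1 to `lambda_min`.
#' @examples
#' round(lambda_ladder(8, 0.426934), 6)
#' @export
lambda_ladder <- function(n, lambda_min = 0.426934) {
  stopifnot(n >= 2)
  if (!is.numeric(lambda_min) || lambda_min <= 0 || lambda_min >= 1)
    stop("invalid ladder: lambda_min must be in (0, 1)")
  lam <- lambda_min^((seq_len(n) - 1) / (n - 1))
  lam[1] <- 1; lam[n] <- lambda_min
  structure(lam, class = "replica_ladder")
}

#' Metropolis exchange probability between two replicas
#'
#' For replicas i and j holding configurations x_i and x_j, the swap is
#' accepted with probability
#' `min(1, exp(-(E_i(x_j) + E_j(x_i) - E_i(x_i) - E_j(x_j)) / kB T))`,
#' where `E_r(x)` is replica r's full energy (scaled Hamiltonian plus walls
#' plus its own bias) evaluated on configuration x. The factor is symmetric
#' under relabeling the two replicas.
#'
#' @param E_i_xi,E_i_xj energy of replica i on its own / the partner's
#'   configuration, kJ/mol.
#' @param E_j_xi,E_j_xj same for replica j.
#' @param temperature K.
#' @return Acceptance probability in [0, 1].
#' @export
exchange_probability <- function(E_i_xi, E_i_xj, E_j_xi, E_j_xj,
                                 temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  stopifnot(is.finite(E_i_xi), is.finite(E_i_xj), is.finite(E_j_xi),
            is.finite(E_j_xj))
  delta <- (E_i_xj + E_j_xi) - (E_i_xi + E_j_xj)
  min(1, exp(-delta / kBT(temperature)))
}

# ---- composable energy terms -------------------------------------------

#' Hamiltonian terms of a sampling system
#'
#' Decomposes a system's energy into named terms, each flagged as
#' solute-scalable or not. In the solute-tempering convention only the
#' force-field terms responsible for barriers (here: the torsion series, or
#' the toy double-well polynomial) are scalable; wall restraints and
#' geometric constraints are part of the unscaled Hamiltonian at every
#' lambda.
#'
#' @param system a [cg_chain_system()] or [double_well_system()].
#' @return An object of class `energy_terms`: a list of terms with fields
#'   `name`, `scalable`, `scale` and `energy(state)`.
#' @export
hamiltonian_terms <- function(system) UseMethod("hamiltonian_terms")

#' Scale the solute-scalable Hamiltonian terms
#'
#' Multiplies the amplitude of every scalable term by `lambda`, leaving
#' walls and constraints untouched; `lambda = 1` is the identity.
#'
#' @param terms an `energy_terms` object from [hamiltonian_terms()].
#' @param lambda scaling factor in (0, 1].
#' @return The scaled `energy_terms`.
#' @export
scale_hamiltonian <- function(terms, lambda) {
  stopifnot(inherits(terms, "energy_terms"))
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  terms$terms <- lapply(terms$terms, function(tm) {
    if (tm$scalable) tm$scale <- tm$scale * lambda
    tm
  })
  terms
}

#' Evaluate composed Hamiltonian terms
#'
#' @param terms an `energy_terms` object.
#' @param state a system state (chain torsions in degrees, or the scalar CV
#'   of the toy system).
#' @return Total energy, kJ/mol.
#' @export
hamiltonian_energy <- function(terms, state) {
  stopifnot(inherits(terms, "energy_terms"))
  sum(vapply(terms$terms, function(tm) tm$scale * tm$energy(state),
             numeric(1)))
}

# ---- systems ------------------------------------------------------------

#' Coarse-grained chain system for the sampling engines
#'
#' Bundles geometry, torsion potential and optional d1 wall into a system
#' the metadynamics/replica-exchange drivers can propagate. The biased CV
#' is d1.
#'
#' @param geometry a [chain_geometry()].
#' @param potential a [torsion_potential()].
#' @param restraint optional [wall_restraint()] on d1.
#' @return An object of class `cg_chain_system`.
#' @export
cg_chain_system <- function(geometry = chain_geometry(),
                            potential = torsion_potential(),
                            restraint = NULL) {
  structure(list(geometry = geometry, potential = potential,
                 restraint = restraint, cv_name = "d1",
                 label = "cg_chain"),
            class = c("cg_chain_system", "mc_system"))
}

#' @export
hamiltonian_terms.cg_chain_system <- function(system) {
  terms <- list(list(
    name = "torsion", scalable = TRUE, scale = 1,
    energy = function(state) sum(torsion_energy(system$potential, state))))
  if (!is.null(system$restraint))
    terms <- c(terms, list(list(
      name = "wall", scalable = FALSE, scale = 1,
      energy = function(state) wall_energy(chain_d1(system$geometry, state),
                                           system$restraint))))
  structure(list(terms = terms), class = "energy_terms")
}

#' One-dimensional double-well system
#'
#' The analytic validation system for the sampling engines: a particle on
#' `V(s) = height * ((s/s0)^2 - 1)^2` with minima at +/-`s0` and barrier
#' `height` at s = 0, sampled by a Gaussian-step Metropolis walk. Because
#' the potential is known in closed form, reconstructed free-energy
#' surfaces can be compared against it exactly.
#'
#' @param height barrier height, kJ/mol.
#' @param s0 half-separation of the minima (CV units, nominally nm).
#' @param step_sd proposal standard deviation.
#' @param domain CV range covered by the bias grid.
#' @return An object of class `double_well_system`.
#' @export
double_well_system <- function(height = 12, s0 = 1, step_sd = 0.15,
                               domain = c(-2.5, 2.5)) {
  stopifnot(height > 0, s0 > 0, step_sd > 0)
  poly <- c(height, 0, -2 * height / s0^2, 0, height / s0^4)
  structure(list(poly = poly, height = height, s0 = s0, step_sd = step_sd,
                 domain = domain, cv_name = "s", label = "toy"),
            class = c("double_well_system", "mc_system"))
}

#' @export
hamiltonian_terms.double_well_system <- function(system) {
  structure(list(terms = list(list(
    name = "double_well", scalable = TRUE, scale = 1,
    energy = function(state) analytic_potential(system, state)))),
    class = "energy_terms")
}

#' Analytic potential of the double-well system
#'
#' @param system a [double_well_system()].
#' @param s CV value(s).
#' @return V(s), kJ/mol.
#' @export
analytic_potential <- function(system, s) {
  drop(outer(s, seq_along(system$poly) - 1, "^") %*% system$poly)
}

# default starting state of a system
initial_state <- function(system) {
  if (inherits(system, "cg_chain_system"))
    rep(180, system$geometry$n_torsions)
  else -system$s0
}

# propagate one replica segment; returns updated state + frames + kernels
propagate_segment <- function(system, state, lambda, bias, deposit, n_sweeps,
                              thin, temperature) {
  if (inherits(system, "cg_chain_system")) {
    g <- system$geometry
    span <- g$n_units * g$all_trans_repeat_length
    res <- chain_mc_cpp(
      psi0 = state, n_sweeps = as.integer(n_sweeps), thin = as.integer(thin),
      ell = g$bond_length, thetas = g$bond_angles,
      tors_bonds = g$torsion_bonds, n_beads = g$n_beads,
      term_a = g$terminal_beads$a, term_b = g$terminal_beads$b,
      coefs = system$potential$coefs, lambda = lambda,
      wall_on = !is.null(system$restraint),
      wall_limit = if (is.null(system$restraint)) 0 else system$restraint$limit,
      wall_k = if (is.null(system$restraint)) 0 else system$restraint$k,
      wall_side = if (!is.null(system$restraint) &&
                        system$restraint$side == "upper") -1L else 1L,
      wall_exp = if (is.null(system$restraint)) 2L else system$restraint$exponent,
      metad_on = !is.null(bias), metad_deposit = deposit,
      centers0 = if (is.null(bias)) numeric(0) else bias$centers[, 1],
      heights0 = if (is.null(bias)) numeric(0) else bias$heights,
      msigma = if (is.null(bias)) 0.05 else bias$sigma,
      mgamma = if (is.null(bias)) 15 else bias$gamma,
      mw0 = if (is.null(bias)) 0.5 else bias$w0,
      mpace = if (is.null(bias)) 0L else as.integer(bias$pace),
      gmin = 0, gmax = span * 1.25, ngrid = 2048L,
      temperature = temperature)
    frames <- data.frame(cv = res$d1, bias = res$bias)
    psi_cols <- as.data.frame(res$psi)
    names(psi_cols) <- paste0("psi", seq_len(ncol(psi_cols)))
    list(state = res$psi_final, frames = cbind(frames, psi_cols),
         centers = res$centers, heights = res$heights,
         acceptance = res$acceptance)
  } else {
    res <- dw_mc_cpp(
      s0 = state, n_steps = as.integer(n_sweeps), thin = as.integer(thin),
      poly = system$poly, lambda = lambda, step_sd = system$step_sd,
      wall_on = FALSE, wall_limit = 0, wall_k = 0, wall_side = 1L,
      wall_exp = 2L,
      metad_on = !is.null(bias), metad_deposit = deposit,
      centers0 = if (is.null(bias)) numeric(0) else bias$centers[, 1],
      heights0 = if (is.null(bias)) numeric(0) else bias$heights,
      msigma = if (is.null(bias)) 0.05 else bias$sigma,
      mgamma = if (is.null(bias)) 15 else bias$gamma,
      mw0 = if (is.null(bias)) 0.5 else bias$w0,
      mpace = if (is.null(bias)) 0L else as.integer(bias$pace),
      gmin = system$domain[1], gmax = system$domain[2], ngrid = 2048L,
      temperature = temperature)
    list(state = res$s_final, frames = data.frame(cv = res$s, bias = res$bias),
         centers = res$centers, heights = res$heights,
         acceptance = res$acceptance)
  }
}

# full replica energy: lambda-scaled Hamiltonian + that replica's own bias
replica_energy <- function(system, terms_scaled, state, bias) {
  e <- hamiltonian_energy(terms_scaled, state)
  if (!is.null(bias) && length(bias$heights) > 0) {
    cv <- if (inherits(system, "cg_chain_system"))
      chain_d1(system$geometry, state) else state
    e <- e + evaluate_bias(bias, cv)
  }
  e
}

#' Run plain well-tempered metadynamics
#'
#' Single-replica convenience wrapper: equivalent to [run_hrex_wtmtd()]
#' with a trivial one-replica ladder.
#'
#' @param system a sampling system.
#' @param bias_spec a [metad_bias()] template (its kernel history should be
#'   empty; it is filled during the run).
#' @param n_sweeps total MC sweeps.
#' @param temperature K.
#' @param seed RNG seed.
#' @param thin record every `thin`-th sweep.
#' @return A list with `trajectory` (cv_trajectory of the run) and `bias`
#'   (the final deposited [metad_bias()]).
#' @export
run_wtmtd <- function(system, bias_spec, n_sweeps, temperature = 300,
                      seed = NULL, thin = 1L) {
  with_seed(seed, {
    seg <- propagate_segment(system, initial_state(system), lambda = 1,
                             bias = bias_spec, deposit = TRUE,
                             n_sweeps = n_sweeps, thin = thin,
                             temperature = temperature)
    traj <- .segment_frames_to_traj(system, list(seg$frames), thin,
                                    temperature, lambda = 1, seed = seed)
    list(trajectory = traj,
         bias = metad_bias_from_kernels(seg$centers, seg$heights, bias_spec),
         acceptance = seg$acceptance)
  })
}

.segment_frames_to_traj <- function(system, frame_list, thin, temperature,
                                    lambda, seed) {
  frames <- do.call(rbind, frame_list)
  df <- data.frame(time = seq_len(nrow(frames)) * thin)
  df[[system$cv_name]] <- frames$cv
  extra_cols <- setdiff(names(frames), c("cv", "bias"))
  for (nm in extra_cols) df[[nm]] <- frames[[nm]]
  df[["metad.bias"]] <- frames$bias
  cv_trajectory(df, temperature = temperature, lambda = lambda,
                system = system$label, seed = seed)
}

#' Combined Hamiltonian replica exchange + well-tempered metadynamics
#'
#' Runs one replica per ladder rung. Replica i evolves under the
#' lambda_i-scaled Hamiltonian (walls unscaled) plus its own well-tempered
#' bias whose Gaussian height is `w0 / lambda_i` ([replica_scaled_height()]).
#' Coordinate swaps between nearest-neighbour rungs are attempted every
#' `exchange_interval` sweeps, alternating even/odd pairs, with the
#' Metropolis factor of [exchange_probability()] evaluated on the full
#' replica energies. Analysis statistics are collected from the unscaled
#' (lambda = 1) replica, which is flagged in the result.
#'
#' @param system a [cg_chain_system()] or [double_well_system()].
#' @param ladder a [lambda_ladder()] (or any vector starting at 1,
#'   non-increasing, in (0, 1]); a single 1 gives plain wt-MTD.
#' @param bias_spec a [metad_bias()] template, or `NULL` for pure HREX.
#'   When depositing, `exchange_interval` must be a multiple of the bias
#'   pace so deposits fall on the same sweeps as in an unsegmented run.
#' @param n_sweeps total sweeps per replica.
#' @param exchange_interval sweeps between exchange attempts.
#' @param temperature K.
#' @param seed RNG seed; the whole run is reproducible from it.
#' @param thin record every `thin`-th sweep (must divide
#'   `exchange_interval`).
#' @return A list with `trajectories` (one cv_trajectory per replica, in
#'   ladder order), `bias` (per-replica final [metad_bias()] or NULL),
#'   `exchange` (data frame of attempts/acceptances per neighbour pair),
#'   `ladder`, and `analysis_replica = 1` marking the unscaled replica.
#' @export
run_hrex_wtmtd <- function(system, ladder, bias_spec = NULL, n_sweeps,
                           exchange_interval = 500L, temperature = 300,
                           seed = NULL, thin = 1L) {
  lam <- as.numeric(ladder)
  stopifnot(length(lam) >= 1, lam[1] == 1, all(lam > 0), all(lam <= 1),
            all(diff(lam) <= 0))
  n_rep <- length(lam)
  if (!is.null(bias_spec)) {
    stopifnot(inherits(bias_spec, "metad_bias"))
    if (exchange_interval %% bias_spec$pace != 0)
      stop("exchange_interval must be a multiple of the bias pace")
  }
  if (exchange_interval %% thin != 0)
    stop("thin must divide exchange_interval")
  n_seg <- as.integer(ceiling(n_sweeps / exchange_interval))

  states <- lapply(lam, function(l) initial_state(system))
  biases <- if (is.null(bias_spec)) vector("list", n_rep) else
    lapply(lam, function(l) {
      b <- bias_spec
      b$w0 <- replica_scaled_height(bias_spec$w0, l)
      b
    })
  terms0 <- hamiltonian_terms(system)
  terms_scaled <- lapply(lam, function(l) scale_hamiltonian(terms0, l))
  frames <- replicate(n_rep, vector("list", n_seg), simplify = FALSE)
  acc <- att <- integer(max(n_rep - 1, 1))

  with_seed(seed, {
    for (sg in seq_len(n_seg)) {
      for (r in seq_len(n_rep)) {
        seg <- propagate_segment(system, states[[r]], lam[r], biases[[r]],
                                 deposit = !is.null(bias_spec),
                                 n_sweeps = exchange_interval, thin = thin,
                                 temperature = temperature)
        states[[r]] <- seg$state
        frames[[r]][[sg]] <- seg$frames
        if (!is.null(bias_spec))
          biases[[r]] <- metad_bias_from_kernels(seg$centers, seg$heights,
                                                 biases[[r]])
      }
      if (n_rep > 1) {
        first <- if (sg %% 2L == 1L) 1L else 2L
        for (i in if (first > n_rep - 1L) integer(0) else
               seq(first, n_rep - 1L, by = 2L)) {
          j <- i + 1L
          E_i_xi <- replica_energy(system, terms_scaled[[i]], states[[i]], biases[[i]])
          E_i_xj <- replica_energy(system, terms_scaled[[i]], states[[j]], biases[[i]])
          E_j_xi <- replica_energy(system, terms_scaled[[j]], states[[i]], biases[[j]])
          E_j_xj <- replica_energy(system, terms_scaled[[j]], states[[j]], biases[[j]])
          p <- exchange_probability(E_i_xi, E_i_xj, E_j_xi, E_j_xj, temperature)
          att[i] <- att[i] + 1L
          if (runif(1) < p) {
            tmp <- states[[i]]; states[[i]] <- states[[j]]; states[[j]] <- tmp
            acc[i] <- acc[i] + 1L
          }
        }
      }
    }
  })

  trajectories <- lapply(seq_len(n_rep), function(r)
    .segment_frames_to_traj(system, frames[[r]], thin, temperature,
                            lambda = lam[r], seed = seed))
  exchange <- if (n_rep > 1)
    data.frame(pair = paste(seq_len(n_rep - 1), 2:n_rep, sep = "-"),
               attempts = att[seq_len(n_rep - 1)],
               acceptances = acc[seq_len(n_rep - 1)],
               rate = ifelse(att[seq_len(n_rep - 1)] > 0,
                             acc[seq_len(n_rep - 1)] / att[seq_len(n_rep - 1)],
                             NA_real_))
  else data.frame(pair = character(0), attempts = integer(0),
                  acceptances = integer(0), rate = numeric(0))
  list(trajectories = trajectories, bias = biases, exchange = exchange,
       ladder = lam, analysis_replica = 1L)
}
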