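#' Coarse-grained PET oligomer geometry
#'
#' Defines the bead-chain geometry of a coarse-grained PET oligomer with
#' `n_units` repeat units, three backbone beads per repeat plus a terminal
#' bead. The two chain ends are carbonyl marker beads; the distance between
#' them is the terminal distance d1 used by the wall restraints that steer
#' the gauche/trans equilibrium. One ethylene-glycol torsion (Psi) per repeat
#' unit is free to rotate; all other dihedrals are fixed trans and bond
#' lengths and angles are rigid.
#'
#' Two bond angles are used: a backbone angle, and a sharper angle at the
#' glycol beads flanking each Psi bond so that a single gauche torsion kinks
#' the chain decisively. The bond length is set from
#' `all_trans_repeat_length` so the fully extended (all-trans) chain spans
#' `n_units * all_trans_repeat_length` between the terminal beads; the
#' default 1.025 nm puts the tetramer's taut length at 4.10 nm, just above
#' the 4.0 nm crystalline-state restraint, so that restraint pulls the chain
#' taut exactly as the corresponding atomistic restraint does.
#'
#' @param n_units number of PET repeat units (>= 2); default 4 (tetramer).
#' @param all_trans_repeat_length nm of terminal-to-terminal span contributed
#'   by each repeat unit in the all-trans state.
#' @param backbone_angle,glycol_angle bond angles in degrees.
#' @return An object of class `chain_geometry`.
#' @examples
#' g <- chain_geometry()
#' g$n_torsions # 4
#' @export
chain_geometry <- function(n_units = 4, all_trans_repeat_length = 1.025,
                           backbone_angle = 114, glycol_angle = 90) {
  stopifnot(n_units >= 2, all_trans_repeat_length > 0,
            backbone_angle > 0, backbone_angle < 180,
            glycol_angle > 0, glycol_angle < 180)
  n_units <- as.integer(n_units)
  n_beads <- 3L * n_units + 1L
  # one Psi bond per repeat unit, symmetric under chain reversal: first-half
  # repeats use their last bond, second-half repeats their first, an odd
  # middle repeat its middle bond
  tors_bonds <- vapply(seq_len(n_units), function(j) {
    if (j <= n_units / 2) 3L * j
    else if (n_units %% 2L == 1L && j == (n_units + 1L) %/% 2L) 3L * j - 1L
    else 3L * j - 2L
  }, integer(1))
  glycol_beads <- sort(unique(c(tors_bonds, tors_bonds + 1L)))
  thetas <- rep(backbone_angle, n_beads - 2L) # angle at bead k+1
  thetas[glycol_beads - 1L] <- glycol_angle
  bead_spec <- rep("backbone", n_beads)
  bead_spec[glycol_beads] <- "glycol"
  bead_spec[c(1L, n_beads)] <- "carbonyl_terminus"

  # bond length from the all-trans span calibration
  unit_coords <- chain_coords_cpp(rep(180, n_units), 1.0, thetas, tors_bonds,
                                  n_beads)
  unit_span <- sqrt(sum((unit_coords[n_beads, ] - unit_coords[1L, ])^2))
  bond_length <- n_units * all_trans_repeat_length / unit_span

  structure(
    list(n_units = n_units, n_beads = n_beads, n_torsions = n_units,
         bead_spec = bead_spec, bond_length = bond_length,
         bond_angles = thetas, torsion_bonds = tors_bonds,
         all_trans_repeat_length = all_trans_repeat_length,
         terminal_beads = list(a = 1L, b = n_beads)),
    class = "chain_geometry"
  )
}

#' @export
print.chain_geometry <- function(x, ...) {
  cat(sprintf(
    "CG PET oligomer: %d repeat units, %d beads, %d Psi torsions\n",
    x$n_units, x$n_beads, x$n_torsions))
  cat(sprintf("  bond length %.4f nm, all-trans span %.3f nm\n",
              x$bond_length, x$n_units * x$all_trans_repeat_length))
  invisible(x)
}

# normalize angles (degrees) to (-180, 180]
normalize_angle <- function(psi) {
  out <- psi - 360 * floor((psi + 180) / 360)
  out[out == -180] <- 180
  out
}

#' Build a chain configuration from its Psi torsions
#'
#' Places all beads by forward kinematics with the geometry's rigid bond
#' lengths and angles, the given ethylene-glycol torsions, and all remaining
#' dihedrals trans.
#'
#' @param geometry a [chain_geometry()].
#' @param psi numeric vector of Psi torsions in degrees, one per repeat unit.
#' @return An object of class `chain_state` with elements `coords`
#'   (n_beads x 3 matrix, nm), `psi` (degrees, normalized to (-180, 180]) and
#'   `geometry`.
#' @examples
#' st <- chain_state(chain_geometry(), rep(180, 4))
#' min_terminal_distance(st) # taut length, 4.10 nm
#' @export
chain_state <- function(geometry, psi) {
  stopifnot(inherits(geometry, "chain_geometry"))
  if (length(psi) != geometry$n_torsions)
    stop("psi must have one angle per repeat unit (", geometry$n_torsions, ")")
  if (any(!is.finite(psi))) stop("non-finite torsion angle")
  psi <- normalize_angle(psi)
  coords <- chain_coords_cpp(psi, geometry$bond_length, geometry$bond_angles,
                             geometry$torsion_bonds, geometry$n_beads)
  structure(list(coords = coords, psi = psi, geometry = geometry),
            class = "chain_state")
}

#' Minimum distance between the terminal carbonyl beads
#'
#' The collective variable d1: the minimum Euclidean distance between the
#' carbonyl marker beads of the two chain termini (minimum over marker pairs
#' when a terminus exposes several markers; the default geometry has one
#' marker per end). No periodic imaging is applied: the model has no box.
#'
#' @param state a [chain_state()].
#' @return d1 in nm.
#' @export
min_terminal_distance <- function(state) {
  stopifnot(inherits(state, "chain_state"))
  term <- state$geometry$terminal_beads
  if (length(term$a) < 1L || length(term$b) < 1L)
    stop("chain must expose two termini")
  pairs <- expand.grid(a = term$a, b = term$b)
  min(sqrt(rowSums(
    (state$coords[pairs$a, , drop = FALSE] -
       state$coords[pairs$b, , drop = FALSE])^2
  )))
}

# d1 for a bare psi vector (internal fast path used by tests and scans)
chain_d1 <- function(geometry, psi) {
  min_terminal_distance(chain_state(geometry, psi))
}

# enumerate d1 over all (trans, gauche+, gauche-) torsion-state combinations;
# used to check the geometric-exclusion property of a geometry
enumerate_d1 <- function(geometry, states = c(180, 70, -70)) {
  grid <- as.matrix(expand.grid(rep(list(states), geometry$n_torsions)))
  data.frame(
    n_gauche = rowSums(abs(grid) < 120),
    d1 = apply(grid, 1L, function(p) chain_d1(geometry, p))
  )
}
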