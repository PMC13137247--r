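# shared objects for the test suite; everything is built in code
kB <- 0.0083144621

default_geom <- chain_geometry()
default_pot <- torsion_potential()

# deterministic quadrature of the single-torsion Boltzmann density
torsion_boltzmann <- function(potential, temperature, psi = seq(-179.95, 180, 0.1)) {
  u <- torsion_energy(potential, psi)
  w <- exp(-(u - min(u)) / (kB * temperature))
  list(psi = psi, density = w / sum(w))
}

quadrature_gauche_fraction <- function(potential, temperature) {
  q <- torsion_boltzmann(potential, temperature)
  sum(q$density[abs(q$psi) < 120])
}
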