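# shared simulation setups for the model systems
two_wells_setup <- function() {
  list(pot = make_potential("two_wells"),
       thermo = thermo_config(),
       stop = stop_criterion("le", -3),
       init = c(3, 0))
}

fe_setup <- function() {
  list(pot = make_potential("faradjian_elber"),
       thermo = thermo_config(),
       stop = stop_criterion("lt", -1),
       init = c(3, 0))
}

# central finite difference of the potential energy
fd_gradient <- function(pot, x, y, h = 1e-5) {
  cbind((potential_energy(pot, x + h, y) - potential_energy(pot, x - h, y)) /
          (2 * h),
        (potential_energy(pot, x, y + h) - potential_energy(pot, x, y - h)) /
          (2 * h))
}
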