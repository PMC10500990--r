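#' Physical constants used throughout the package
#'
#' Energies and frequencies are expressed in eV, time in fs, transition
#' dipoles in atomic units, and nuclear coordinates are dimensionless
#' (frequency-scaled) normal coordinates, so that the uncoupled nuclear
#' Hamiltonian reads H0 = sum_a w_a (p_a^2 + q_a^2) / 2.
#'
#' @format `hbar_ev_fs` is the reduced Planck constant in eV fs;
#'   `hartree_ev` is one hartree in eV.
#' @name constants
NULL

#' @rdname constants
#' @export
hbar_ev_fs <- 0.6582119569

#' @rdname constants
#' @export
hartree_ev <- 27.211386245988
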