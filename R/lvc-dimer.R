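#' Fragment-level LVC data for one monomer
#'
#' Everything the dimer assembly needs from a single chromophore: the
#' two quasi-degenerate local excitations |L>, |L'> (energies, gradients
#' g, g', transition dipoles, Jahn-Teller linear coupling vector
#' lambda_LL'), the ionic-species gradients used to approximate CT-state
#' gradients (cation g+, anions g-, g-'), and the vertical energies
#' assigned to CT states that place the transferred electron on this
#' fragment (in L or L + 1).
#'
#' @param modes a [mode_basis] for the monomer (N modes).
#' @param e_le,e_lep vertical energies of |L> and |L'> in eV.
#' @param g,gp gradients of |L> and |L'> (length N, eV).
#' @param lambda_jt Jahn-Teller linear coupling vector between |L> and
#'   |L'> (length N, eV).
#' @param g_cation cation gradient g+ (length N, eV).
#' @param g_anion,g_anionp anion gradients g-, g-' with the electron in
#'   L / L + 1 (length N, eV).
#' @param mu_le,mu_lep transition dipoles of |L> and |L'> (a.u.).
#' @param e_ct,e_ctp vertical energies of the CT states with the
#'   electron transferred into this fragment's L / L + 1 orbital (eV).
#' @return An object of class `fragment_data`.
#' @export
fragment_data <- function(modes, e_le, e_lep, g, gp, lambda_jt,
                          g_cation, g_anion, g_anionp,
                          mu_le, mu_lep, e_ct, e_ctp) {
  stopifnot(inherits(modes, "mode_basis"))
  n <- modes$n
  vecs <- list(g = g, gp = gp, lambda_jt = lambda_jt, g_cation = g_cation,
               g_anion = g_anion, g_anionp = g_anionp)
  for (nm in names(vecs)) {
    if (length(vecs[[nm]]) != n)
      stop(sprintf("fragment vector '%s' must have length %d", nm, n),
           call. = FALSE)
  }
  structure(list(modes = modes, e_le = e_le, e_lep = e_lep,
                 g = as.numeric(g), gp = as.numeric(gp),
                 lambda_jt = as.numeric(lambda_jt),
                 g_cation = as.numeric(g_cation),
                 g_anion = as.numeric(g_anion),
                 g_anionp = as.numeric(g_anionp),
                 mu_le = as.numeric(mu_le), mu_lep = as.numeric(mu_lep),
                 e_ct = as.numeric(e_ct), e_ctp = as.numeric(e_ctp)),
            class = "fragment_data")
}

#' Dimer state ordering
#'
#' Fixed ordering of the eight diabatic states of an LE/CT dimer model.
#' @return Character vector of the eight state labels.
#' @export
dimer_state_labels <- function() {
  c("L1", "L1p", "L2", "L2p", "CT12", "CT12p", "CT21", "CT21p")
}

#' Assemble an eight-state dimer LVC Hamiltonian from two fragments
#'
#' Builds the dimer Hamiltonian on stacked monomer coordinates
#' q_dim = (q1, q2), with the four local excitations |L1>, |L1'>, |L2>,
#' |L2'> and the four charge-transfer states |CT(1->2)>, |CT'(1->2)>,
#' |CT(2->1)>, |CT'(2->1)> (the arrow points from the fragment hosting
#' the hole to the one receiving the electron). LE gradients are
#' block-padded with zeros, e.g. g(L1) = (g_A, 0) and g(L2) = (0, g_B);
#' CT gradients are concatenated ionic gradients, e.g.
#' g(CT(1->2)) = (g+_A, g-_B) and g(CT'(1->2)) = (g+_A, g-'_B). All
#' inter-state couplings are constants taken from `constant_couplings`
#' except the two intra-monomer Jahn-Teller pairs (|L_i>, |L_i'>), which
#' carry the fragment's linear coupling vector (zero-padded onto the
#' other monomer's block) and a zero constant term. CT states are dark
#' (zero dipole).
#'
#' @param frag1,frag2 [fragment_data] objects sharing the mode count N.
#' @param constant_couplings symmetric 8 x 8 matrix of E_ij(0) (eV) in
#'   the [dimer_state_labels()] ordering, zero diagonal. Entries for the
#'   two JT pairs (1,2) and (3,4) must be zero.
#' @param metadata optional provenance list.
#' @return An [lvc_hamiltonian] with 2N modes and 8 states.
#' @export
assemble_dimer_hamiltonian <- function(frag1, frag2, constant_couplings,
                                       metadata = list()) {
  stopifnot(inherits(frag1, "fragment_data"), inherits(frag2, "fragment_data"))
  n <- frag1$modes$n
  if (frag2$modes$n != n)
    stop("fragments must share the same number of modes", call. = FALSE)
  J <- as.matrix(constant_couplings)
  if (!all(dim(J) == c(8L, 8L)) || max(abs(J - t(J))) > 1e-12)
    stop("constant_couplings must be a symmetric 8 x 8 matrix", call. = FALSE)
  if (any(diag(J) != 0))
    stop("constant_couplings must have a zero diagonal", call. = FALSE)
  if (abs(J[1, 2]) > 0 || abs(J[3, 4]) > 0)
    stop("the JT pairs (1,2) and (3,4) take linear couplings; their constant term must be zero",
         call. = FALSE)
  z <- rep(0, n)
  modes <- mode_basis(c(frag1$modes$frequencies, frag2$modes$frequencies),
                      c(paste0("m1:", frag1$modes$labels),
                        paste0("m2:", frag2$modes$labels)))
  lab <- dimer_state_labels()
  states <- list(
    diabatic_state(lab[1], "LE", frag1$e_le,  c(frag1$g,  z), frag1$mu_le),
    diabatic_state(lab[2], "LE", frag1$e_lep, c(frag1$gp, z), frag1$mu_lep),
    diabatic_state(lab[3], "LE", frag2$e_le,  c(z, frag2$g),  frag2$mu_le),
    diabatic_state(lab[4], "LE", frag2$e_lep, c(z, frag2$gp), frag2$mu_lep),
    # electron into fragment 2 (hole on 1) ...
    diabatic_state(lab[5], "CT", frag2$e_ct,  c(frag1$g_cation, frag2$g_anion)),
    diabatic_state(lab[6], "CT", frag2$e_ctp, c(frag1$g_cation, frag2$g_anionp)),
    # ... and into fragment 1 (hole on 2)
    diabatic_state(lab[7], "CT", frag1$e_ct,  c(frag1$g_anion,  frag2$g_cation)),
    diabatic_state(lab[8], "CT", frag1$e_ctp, c(frag1$g_anionp, frag2$g_cation)))
  couplings <- list(
    interstate_coupling(1, 2, 0, c(frag1$lambda_jt, z)),
    interstate_coupling(3, 4, 0, c(z, frag2$lambda_jt)))
  for (i in 1:7) for (j in (i + 1):8) {
    if ((i == 1 && j == 2) || (i == 3 && j == 4)) next
    if (J[i, j] != 0) couplings <- c(couplings, list(interstate_coupling(i, j, J[i, j])))
  }
  lvc_hamiltonian(modes, states, couplings, metadata = metadata)
}
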