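#' Seeded generators for test and benchmark inputs
#'
#' Every generator is deterministic given its arguments (and, where
#' randomness is involved, an explicit seed applied to a local RNG
#' stream), so identical configurations produce bit-identical outputs.
#'
#' @name synthetic-generators
NULL

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Displaced-oscillator monomer model
#'
#' Single bright excited state with vertical energy `e_vertical` and
#' per-mode Huang-Rhys factors `S` (gradients lambda_a =
#' w_a sqrt(2 S_a)), the textbook FC|VG vibronic-progression model.
#'
#' @param e_vertical vertical energy (eV).
#' @param omega mode frequencies (eV).
#' @param S Huang-Rhys factors (recycled to `length(omega)`).
#' @param dipole transition dipole (a.u.).
#' @return An [lvc_hamiltonian].
#' @export
make_displaced_monomer <- function(e_vertical = 2.0, omega = 0.15, S = 0.5,
                                   dipole = c(1, 0, 0)) {
  S <- rep_len(S, length(omega))
  if (any(S < 0)) stop("Huang-Rhys factors must be >= 0", call. = FALSE)
  modes <- mode_basis(omega)
  lam <- omega * sqrt(2 * S)
  lvc_hamiltonian(modes,
                  list(diabatic_state("S1", "LE", e_vertical, lam, dipole)),
                  metadata = list(generator = "displaced_monomer"))
}

#' Jahn-Teller two-state monomer model
#'
#' Two quasi-degenerate local excitations with opposite tuning gradients
#' (+/- kappa) and a linear (not constant) inter-state coupling vector,
#' the situation of the two lowest states of a fourfold-symmetric
#' chromophore. With one tuning and one coupling mode of equal
#' frequency and `kappa` on the tuning mode only this is the E x e
#' model, whose adiabatic surfaces meet in a conical intersection at
#' q = 0 when the splitting is zero.
#'
#' @param energy mean vertical energy (eV).
#' @param omega mode frequencies (eV).
#' @param kappa tuning gradient per mode (eV; state 1 gets +kappa, state
#'   2 gets -kappa).
#' @param jt linear inter-state coupling vector (eV).
#' @param splitting energy asymmetry between the two states (eV).
#' @param dipoles 3 x 2 matrix of transition dipoles (default unit x and
#'   y, the two in-plane polarizations).
#' @return An [lvc_hamiltonian].
#' @export
make_jt_monomer <- function(energy = 2.0, omega = c(0.1, 0.1),
                            kappa = c(0.1, 0), jt = c(0, 0.1),
                            splitting = 0,
                            dipoles = cbind(c(1, 0, 0), c(0, 1, 0))) {
  kappa <- rep_len(kappa, length(omega))
  jt <- rep_len(jt, length(omega))
  modes <- mode_basis(omega)
  states <- list(
    diabatic_state("L", "LE", energy - splitting / 2, kappa, dipoles[, 1]),
    diabatic_state("Lp", "LE", energy + splitting / 2, -kappa, dipoles[, 2]))
  couplings <- if (any(jt != 0)) list(interstate_coupling(1, 2, 0, jt)) else list()
  lvc_hamiltonian(modes, states, couplings,
                  metadata = list(generator = "jt_monomer"))
}

#' Kasha-type LE/CT dimer model
#'
#' Full eight-state dimer template (4 LE + 4 CT in the standard
#' ordering) assembled from two identical fragments: degenerate local
#' excitations at `e_le` with exciton coupling `j_coupling` between
#' like-polarized LEs on different monomers, dark CT states at
#' `e_le + ct_offset` coupled to the LEs by the electron/hole transfer
#' integral `t_lect`, and optional CT-CT coupling and intra-monomer JT
#' linear coupling. The H geometry stacks parallel transition dipoles
#' (bright upper exciton, blue-shifted absorption); the J geometry
#' flips the dipoles of monomer 2 (bright lower exciton).
#'
#' @param e_le LE vertical energy (eV).
#' @param j_coupling exciton (LE-LE) coupling J (eV).
#' @param ct_offset CT energy above the LEs (eV).
#' @param t_lect LE-CT transfer integral (eV).
#' @param t_ctct CT-CT coupling (eV).
#' @param S Huang-Rhys factor(s) of the LE gradients.
#' @param omega monomer mode frequencies (eV); the default single
#'   0.15 eV mode keeps the full dimer exactly propagatable in seconds,
#'   `omega = c(0.15, 0.075)` gives the two-mode (tuning + coupling)
#'   monomer.
#' @param ion_fraction cation/anion gradients as a fraction of the LE
#'   gradient (sets the CT reorganization energy).
#' @param jt intra-monomer JT linear coupling amplitude on the modes.
#' @param geometry `"H"` or `"J"` dipole arrangement.
#' @return An [lvc_hamiltonian] with 8 states and `2 * length(omega)`
#'   modes.
#' @export
make_kasha_ct_dimer <- function(e_le = 2.0, j_coupling = 0.05,
                                ct_offset = 0.3, t_lect = 0.05, t_ctct = 0,
                                S = 0.3, omega = 0.15, ion_fraction = 0.5,
                                jt = 0, geometry = c("H", "J")) {
  geometry <- match.arg(geometry)
  S <- rep_len(S, length(omega))
  jt <- rep_len(jt, length(omega))
  modes <- mode_basis(omega)
  g <- omega * sqrt(2 * S)
  mu1 <- c(1, 0, 0); mu1p <- c(0, 1, 0)
  sgn <- if (geometry == "H") 1 else -1
  frag <- function(mu_le, mu_lep)
    fragment_data(modes, e_le = e_le, e_lep = e_le, g = g, gp = g,
                  lambda_jt = jt, g_cation = ion_fraction * g,
                  g_anion = ion_fraction * g, g_anionp = ion_fraction * g,
                  mu_le = mu_le, mu_lep = mu_lep,
                  e_ct = e_le + ct_offset, e_ctp = e_le + ct_offset)
  J <- matrix(0, 8, 8)
  J[1, 3] <- J[2, 4] <- j_coupling          # like-polarized exciton couplings
  if (t_lect != 0) {
    # electron/hole transfer couples each LE to the CT states sharing its
    # orbital character
    J[1, 5] <- J[3, 5] <- J[1, 7] <- J[3, 7] <- t_lect
    J[2, 6] <- J[4, 6] <- J[2, 8] <- J[4, 8] <- t_lect
  }
  if (t_ctct != 0) {
    J[5, 7] <- J[6, 8] <- t_ctct
  }
  J <- J + t(J)
  assemble_dimer_hamiltonian(frag(mu1, mu1p), frag(sgn * mu1, sgn * mu1p), J,
                             metadata = list(generator = "kasha_ct_dimer",
                                             geometry = geometry))
}

ring_template <- function() {
  # idealized phthalocyanine-like macrocycle: metal center, four pyrrole
  # nitrogens, eight ring carbons
  ang_n <- c(0, 90, 180, 270) * pi / 180
  ang_c <- (c(0, 90, 180, 270, 45, 135, 225, 315) + 22.5) * pi / 180
  rbind(c(0, 0, 0),
        cbind(2.0 * cos(ang_n), 2.0 * sin(ang_n), 0),
        cbind(3.3 * cos(ang_c), 3.3 * sin(ang_c), 0))
}

#' Selection map for the synthetic stacked-ring dimer
#'
#' @return selection list matching [make_stacked_trajectory()] frames.
#' @export
stacked_dimer_selections <- function() {
  na <- nrow(ring_template())
  list(ring1 = seq_len(na), ring2 = na + seq_len(na),
       metal1 = 1L, metal2 = na + 1L,
       axes1 = cbind(rep(1L, 4), 2:5),
       axes2 = cbind(rep(na + 1L, 4), na + 2:5))
}

stacked_frame <- function(d, twist_deg, tilt_deg) {
  ring <- ring_template()
  tw <- twist_deg * pi / 180
  ti <- tilt_deg * pi / 180
  rz <- matrix(c(cos(tw), sin(tw), 0, -sin(tw), cos(tw), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ti), sin(ti), 0, -sin(ti), cos(ti)), 3, 3)
  ring2 <- ring %*% t(rz) %*% t(rx)
  ring2[, 3] <- ring2[, 3] + d
  rbind(ring, ring2)
}

#' Synthetic stacked-ring dimer trajectory with planted clusters
#'
#' Generates frames around a list of conformer centers, each defined by
#' a stacking distance d (Angstrom), a twist about the stacking axis
#' (degrees) and a tilt of the second ring (degrees), plus seeded
#' per-coordinate Gaussian jitter. The defaults plant three clusters of
#' 12, 5 and 3 frames around distinct arrangements whose mutual RMSD is
#' well above twice the standard 0.10 nm clustering cutoff, with
#' within-cluster noise well below half the cutoff, so recovery of the
#' planted structure is well-conditioned. Ground-truth labels are
#' attached as attribute `"labels"`.
#'
#' @param centers data frame (or matrix) with columns `d`, `twist`,
#'   `tilt`, one row per planted conformer.
#' @param frames_per_cluster integer vector, frames per center.
#' @param noise per-coordinate Gaussian jitter sd in Angstrom.
#' @param seed RNG seed for the jitter stream.
#' @return A [conformer_ensemble()] with ground-truth labels.
#' @export
make_stacked_trajectory <- function(centers = data.frame(
                                      d = c(3.4, 4.6, 5.8),
                                      twist = c(0, 80, -80),
                                      tilt = c(0, 30, -35)),
                                    frames_per_cluster = c(12, 5, 3),
                                    noise = 0.05, seed = 1) {
  centers <- as.data.frame(centers)
  if (nrow(centers) != length(frames_per_cluster))
    stop("one frame count per center is required", call. = FALSE)
  na <- 2L * nrow(ring_template())
  nf <- sum(frames_per_cluster)
  coords <- array(0, c(nf, na, 3L))
  labels <- integer(nf)
  f <- 0L
  with_local_seed(seed, {
    for (k in seq_len(nrow(centers))) {
      base <- stacked_frame(centers$d[k], centers$twist[k], centers$tilt[k])
      for (r in seq_len(frames_per_cluster[k])) {
        f <- f + 1L
        jitter <- matrix(stats::rnorm(na * 3L, sd = noise), na, 3L)
        coords[f, , ] <- base + jitter
        labels[f] <- k
      }
    }
  })
  ens <- conformer_ensemble(coords, stacked_dimer_selections())
  attr(ens, "labels") <- labels
  ens
}
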