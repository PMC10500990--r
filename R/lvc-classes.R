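#' Harmonic mode basis
#'
#' Defines the set of dimensionless ground-state normal coordinates an
#' LVC Hamiltonian lives on. A zero-mode basis is allowed and describes a
#' purely electronic Hamiltonian (useful e.g. for Rabi-type models).
#'
#' @param frequencies numeric vector of mode frequencies w_a in eV
#'   (all > 0; may be empty).
#' @param labels optional character vector of mode tags.
#' @return An object of class `mode_basis` with fields `frequencies`,
#'   `n` and `labels`.
#' @export
mode_basis <- function(frequencies = numeric(0), labels = NULL) {
  frequencies <- as.numeric(frequencies)
  if (anyNA(frequencies) || any(frequencies <= 0))
    stop("all mode frequencies must be positive and finite", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (length(frequencies)) paste0("q", seq_along(frequencies)) else character(0)
  }
  if (length(labels) != length(frequencies))
    stop("labels must match the number of modes", call. = FALSE)
  structure(list(frequencies = frequencies, n = length(frequencies),
                 labels = as.character(labels)),
            class = "mode_basis")
}

#' Diabatic electronic state
#'
#' A diabatic state of fixed electronic character: a local excitation
#' (`"LE"`) carrying a transition dipole from the ground state, or a
#' charge-transfer state (`"CT"`) which is dark by construction (its
#' dipole must be the zero vector).
#'
#' @param label state name.
#' @param character `"LE"` or `"CT"`.
#' @param energy0 vertical diabatic energy E_ii(0) at the reference
#'   geometry, in eV.
#' @param gradient intra-state linear coupling (gradient) vector
#'   lambda_ii in eV, one entry per mode.
#' @param dipole length-3 transition dipole <g|mu|i> in atomic units.
#' @return An object of class `diabatic_state`.
#' @export
diabatic_state <- function(label, character = c("LE", "CT"), energy0,
                           gradient = numeric(0), dipole = c(0, 0, 0)) {
  character <- match.arg(character)
  gradient <- as.numeric(gradient)
  dipole <- as.numeric(dipole)
  if (length(dipole) != 3L)
    stop("dipole must be a 3-vector", call. = FALSE)
  if (character == "CT" && any(dipole != 0))
    stop("CT states are dark: dipole must be the zero vector", call. = FALSE)
  if (!is.numeric(energy0) || length(energy0) != 1L || !is.finite(energy0))
    stop("energy0 must be a finite scalar (eV)", call. = FALSE)
  structure(list(label = as.character(label), character = character,
                 energy0 = as.numeric(energy0), gradient = gradient,
                 dipole = dipole),
            class = "diabatic_state")
}

#' Inter-state coupling
#'
#' Coupling between diabatic states i < j: a constant term E_ij(0) and,
#' only for Jahn-Teller pairs, a linear coupling vector lambda_ij. For
#' JT pairs the linear term is the leading one and the constant term is
#' typically zero.
#'
#' @param i,j state indices (i < j after normalization).
#' @param constant E_ij(0) in eV.
#' @param linear optional lambda_ij vector in eV (length = number of
#'   modes); `NULL` means lambda_ij = 0.
#' @return An object of class `interstate_coupling`.
#' @export
interstate_coupling <- function(i, j, constant = 0, linear = NULL) {
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("coupling requires two distinct states", call. = FALSE)
  if (i > j) { tmp <- i; i <- j; j <- tmp }   # symmetric under pair swap
  if (!is.null(linear)) linear <- as.numeric(linear)
  structure(list(i = i, j = j, constant = as.numeric(constant), linear = linear),
            class = "interstate_coupling")
}

#' Linear vibronic coupling Hamiltonian
#'
#' Container for an LVC Hamiltonian
#' H = sum_a w_a (p_a^2 + q_a^2)/2 + V(q) with
#' V_ii(q) = E_ii(0) + lambda_ii . q (harmonic part shared) and
#' V_ij(q) = E_ij(0) + lambda_ij . q. After a hierarchical effective-mode
#' rotation the diagonal frequency matrix generalizes to a dense
#' symmetric `mode_coupling` matrix W entering both kinetic and
#' potential bilinear terms, sum_ab W_ab (p_a p_b + q_a q_b)/2.
#'
#' @param modes a [mode_basis].
#' @param states list of [diabatic_state] objects.
#' @param couplings list of [interstate_coupling] objects.
#' @param mode_coupling optional dense symmetric frequency matrix W
#'   (eV); defaults to diag(frequencies).
#' @param metadata free-form provenance list.
#' @return An object of class `lvc_hamiltonian`.
#' @export
lvc_hamiltonian <- function(modes, states, couplings = list(),
                            mode_coupling = NULL, metadata = list()) {
  stopifnot(inherits(modes, "mode_basis"))
  if (!length(states)) stop("at least one diabatic state is required", call. = FALSE)
  for (s in states) {
    stopifnot(inherits(s, "diabatic_state"))
    if (length(s$gradient) != modes$n)
      stop(sprintf("state '%s': gradient length %d != number of modes %d",
                   s$label, length(s$gradient), modes$n), call. = FALSE)
  }
  ns <- length(states)
  seen <- character(0)
  for (cp in couplings) {
    stopifnot(inherits(cp, "interstate_coupling"))
    if (cp$j > ns) stop("coupling refers to a state index out of range", call. = FALSE)
    key <- paste(cp$i, cp$j)
    if (key %in% seen) stop("duplicate coupling for pair ", key, call. = FALSE)
    seen <- c(seen, key)
    if (!is.null(cp$linear) && length(cp$linear) != modes$n)
      stop("linear coupling vector length must equal the number of modes", call. = FALSE)
  }
  if (is.null(mode_coupling)) {
    mode_coupling <- diag(modes$frequencies, nrow = modes$n)
  } else {
    mode_coupling <- as.matrix(mode_coupling)
    if (!isTRUE(all.equal(dim(mode_coupling), c(modes$n, modes$n))) ||
        max(abs(mode_coupling - t(mode_coupling))) > 1e-12)
      stop("mode_coupling must be a symmetric N x N matrix", call. = FALSE)
  }
  structure(list(modes = modes, states = states, couplings = couplings,
                 mode_coupling = mode_coupling, metadata = metadata),
            class = "lvc_hamiltonian")
}

#' @exportS3Method base::print
print.lvc_hamiltonian <- function(x, ...) {
  chars <- vapply(x$states, `[[`, character(1), "character")
  cat(sprintf("LVC Hamiltonian: %d states (%d LE, %d CT), %d modes\n",
              length(x$states), sum(chars == "LE"), sum(chars == "CT"),
              x$modes$n))
  cat(sprintf("  vertical energies [eV]: %s\n",
              paste(sprintf("%.4f", vapply(x$states, `[[`, numeric(1), "energy0")),
                    collapse = " ")))
  njt <- sum(vapply(x$couplings, function(cp) !is.null(cp$linear), logical(1)))
  cat(sprintf("  couplings: %d constant, %d with linear (JT) terms\n",
              length(x$couplings) - njt, njt))
  if (max(abs(x$mode_coupling - diag(diag(x$mode_coupling), nrow = x$modes$n))) > 0)
    cat("  dense mode-coupling (bilinear) frequency matrix present\n")
  invisible(x)
}

#' @exportS3Method base::print
print.mode_basis <- function(x, ...) {
  cat(sprintf("mode basis: %d modes, frequencies [eV]: %s\n", x$n,
              paste(sprintf("%.4f", x$frequencies), collapse = " ")))
  invisible(x)
}

n_states <- function(H) length(H$states)

state_characters <- function(H) vapply(H$states, `[[`, character(1), "character")

state_labels <- function(H) vapply(H$states, `[[`, character(1), "label")

state_energies <- function(H) vapply(H$states, `[[`, numeric(1), "energy0")

state_gradients <- function(H) {
  # N x n_states matrix (zero-row matrix when N = 0)
  matrix(unlist(lapply(H$states, `[[`, "gradient")), nrow = H$modes$n)
}

state_dipoles <- function(H) {
  matrix(unlist(lapply(H$states, `[[`, "dipole")), nrow = 3L)
}

#' Constant-coupling matrix of an LVC Hamiltonian
#'
#' @param H an [lvc_hamiltonian].
#' @return Symmetric n_states x n_states matrix of E_ij(0) (diagonal =
#'   vertical energies).
#' @export
electronic_matrix <- function(H) {
  ns <- n_states(H)
  E <- diag(state_energies(H), nrow = ns)
  for (cp in H$couplings) {
    E[cp$i, cp$j] <- E[cp$j, cp$i] <- cp$constant
  }
  dimnames(E) <- list(state_labels(H), state_labels(H))
  E
}

# lambda_ij vectors as an N x n_pairs matrix together with the pair list
linear_couplings <- function(H) {
  keep <- Filter(function(cp) !is.null(cp$linear) && any(cp$linear != 0), H$couplings)
  list(pairs = lapply(keep, function(cp) c(cp$i, cp$j)),
       vectors = lapply(keep, `[[`, "linear"))
}
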