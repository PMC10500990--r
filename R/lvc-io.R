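#' Write an LVC Hamiltonian to a structured parameter file
#'
#' The file is JSON with sections `modes`, `states` and `couplings`,
#' serialized to 17 significant digits so that a read/write round trip
#' is lossless at full double precision. The metadata block reserves a
#' `delta_numdiff` field recording the displacement step used when the
#' parameters were obtained by numerical differentiation (informational
#' only; parameters are inputs here).
#'
#' @param H an [lvc_hamiltonian].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lvc <- function(H, path) {
  stopifnot(inherits(H, "lvc_hamiltonian"))
  obj <- list(
    format = "lvc-parameters",
    version = 1L,
    metadata = c(H$metadata,
                 if (is.null(H$metadata$delta_numdiff)) list(delta_numdiff = NULL)),
    modes = list(frequencies = H$modes$frequencies, labels = H$modes$labels),
    states = lapply(H$states, function(s)
      list(label = s$label, character = s$character, energy0 = s$energy0,
           gradient = s$gradient, dipole = s$dipole)),
    couplings = lapply(H$couplings, function(cp)
      list(i = cp$i, j = cp$j, constant = cp$constant, linear = cp$linear)))
  nondiag <- H$mode_coupling - diag(diag(H$mode_coupling), nrow = H$modes$n)
  if (H$modes$n && max(abs(nondiag)) > 0)
    obj$mode_coupling <- H$mode_coupling
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

#' Read an LVC Hamiltonian from a parameter file
#'
#' Inverse of [write_lvc()]. Unknown keys are rejected rather than
#' ignored, so silent typos in hand-edited files cannot change a model.
#'
#' @param path path to a JSON parameter file.
#' @return An [lvc_hamiltonian].
#' @export
read_lvc <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  check_keys(obj, c("format", "version", "metadata", "modes", "states",
                    "couplings", "mode_coupling"), "parameter file")
  if (!identical(obj$format, "lvc-parameters"))
    stop("not an LVC parameter file", call. = FALSE)
  check_keys(obj$modes, c("frequencies", "labels"), "modes section")
  modes <- mode_basis(obj$modes$frequencies, obj$modes$labels)
  states <- lapply(obj$states, function(s) {
    check_keys(s, c("label", "character", "energy0", "gradient", "dipole"),
               sprintf("state '%s'", s$label))
    diabatic_state(s$label, s$character, s$energy0,
                   if (is.null(s$gradient)) numeric(0) else s$gradient,
                   s$dipole)
  })
  couplings <- lapply(obj$couplings, function(cp) {
    check_keys(cp, c("i", "j", "constant", "linear"), "coupling")
    interstate_coupling(cp$i, cp$j, cp$constant, cp$linear)
  })
  md <- if (is.null(obj$metadata)) list() else obj$metadata
  lvc_hamiltonian(modes, states, couplings,
                  mode_coupling = obj$mode_coupling, metadata = md)
}

#' Import gradient vectors from a tabular CSV file
#'
#' Reads a CSV with one row per mode: a `frequency` column (eV) and one
#' named column per gradient vector.
#'
#' @param path CSV path.
#' @return list with `modes` (a [mode_basis]) and `gradients` (named
#'   list of numeric vectors).
#' @export
read_gradients_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"frequency" %in% names(df))
    stop("gradient CSV must have a 'frequency' column", call. = FALSE)
  modes <- mode_basis(df$frequency)
  grads <- as.list(df[setdiff(names(df), "frequency")])
  list(modes = modes, gradients = lapply(grads, as.numeric))
}
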