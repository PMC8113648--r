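# Physical constants and unit conversions.
#
# All geometry is specified in nanometres; the solver works in SI
# (metres, seconds, mol, mol/m^3).  1 uM = 1e-3 mol/m^3, 1 nM = 1e-6 mol/m^3.

#' Physical constants used throughout the package
#'
#' Faraday constant (C/mol) and Avogadro number (1/mol).
#'
#' @format A named list with elements `faraday` and `avogadro`.
#' @export
socesim_constants <- list(
  faraday  = 96485.33212,
  avogadro = 6.02214076e23
)

NM  <- 1e-9   # nm -> m
UM2_S <- 1e-12 # um^2/s -> m^2/s
MOLM3_PER_UM <- 1e-3 # uM -> mol/m^3
MOLM3_PER_NM <- 1e-6 # nM -> mol/m^3

#' Convert concentrations between display units and mol/m^3
#'
#' @param x numeric vector.
#' @name unit-conversion
#' @return numeric vector in the target unit.
#' @export
uM_to_molm3 <- function(x) x * MOLM3_PER_UM

#' @rdname unit-conversion
#' @export
molm3_to_uM <- function(x) x / MOLM3_PER_UM

#' @rdname unit-conversion
#' @export
nM_to_molm3 <- function(x) x * MOLM3_PER_NM

#' @rdname unit-conversion
#' @export
molm3_to_nM <- function(x) x / MOLM3_PER_NM

# internal condition helpers ------------------------------------------------

abort_socesim <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "socesim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

invalid_argument <- function(msg, ...) {
  abort_socesim("socesim_invalid_argument", msg, ...)
}

geometry_violation <- function(msg, ...) {
  abort_socesim("socesim_geometry_violation", msg, ...)
}

mesh_resolution_error <- function(msg, ...) {
  abort_socesim("socesim_mesh_resolution_error", msg, ...)
}

solver_failure <- function(msg, ...) {
  abort_socesim("socesim_solver_failure", msg, ...)
}

usage_error <- function(msg, ...) {
  abort_socesim("socesim_usage_error", msg, ...)
}
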