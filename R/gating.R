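# Boundary flux laws: the discrete ORAI1 open-fraction function of sensed ER
# calcium, ORAI1 and IP3R molar rates, and bidirectional SERCA pump kinetics.

#' Discrete ORAI1 open-fraction table
#'
#' The ORAI1 open fraction f takes discrete values in \[0, 1\], determined by
#' the locally sensed ER calcium concentration: STIM2-bound ORAI1 opens only
#' minimally (21% of the unitary current) when the ER is full, half-maximally
#' once the sensed ER calcium falls to ~330 uM, and progressively more with
#' deeper local depletion.  The default bands are anchored at the three
#' regimes above: f = 0.21 for sensed calcium >= 360 uM, 0.5 on
#' \[250, 360) uM, 0.79 on \[150, 250) uM and 1.0 below 150 uM.
#'
#' @param thresholds strictly descending ER-calcium breakpoints (uM).
#' @param fractions open fractions, one more entry than `thresholds`,
#'   non-decreasing as the ER empties (i.e. non-increasing in sensed calcium).
#' @return An object of class `gating_table`.
#' @export
gating_table <- function(thresholds = c(360, 250, 150),
                         fractions = c(0.21, 0.50, 0.79, 1.00)) {
  if (length(fractions) != length(thresholds) + 1)
    invalid_argument("need one more fraction than thresholds")
  if (any(diff(thresholds) >= 0))
    invalid_argument("thresholds must be strictly descending")
  if (any(fractions < 0 | fractions > 1))
    invalid_argument("fractions must lie in [0, 1]")
  if (any(diff(fractions) < 0))
    invalid_argument("fractions must not decrease as the ER empties")
  structure(list(thresholds = thresholds, fractions = fractions),
            class = "gating_table")
}

#' ORAI1 open fraction for a sensed ER calcium concentration
#'
#' Piecewise-constant lookup in a [gating_table()].
#'
#' @param table a [gating_table()].
#' @param cs_loc sensed ER calcium (uM); vectorised.
#' @return open fraction(s) in \[0, 1\].
#' @examples
#' orai_open_fraction(gating_table(), 400)  # 0.21, full ER
#' orai_open_fraction(gating_table(), 330)  # 0.50, locally depleted ER
#' @export
orai_open_fraction <- function(table, cs_loc) {
  if (any(cs_loc < 0)) invalid_argument("cs_loc must be >= 0")
  idx <- vapply(cs_loc, function(c) 1L + sum(c < table$thresholds), 0L)
  table$fractions[idx]
}

#' Flux and diffusion parameters
#'
#' Defaults: unitary (fully open) ORAI1 current 2.1 fA, unitary IP3R current
#' 0.064 pA at the resting concentration difference, resting ER calcium
#' 400 uM, resting cytosolic calcium 30 nM, cytosolic and ER diffusion
#' coefficients 220 and 10 um^2/s.  The SERCA pump is a bidirectional
#' second-order Hill pump; its luminal constant `serca_KS` is fixed by the
#' rest-equilibrium constraint `serca_KS / serca_KC = C_S0 / C_C0`, so the
#' net pump flux vanishes exactly at resting concentrations.
#'
#' @param I_ORAI unitary full-open ORAI1 current (A).
#' @param I_IP3R unitary IP3R current at the resting gradient (A).
#' @param C_S0 resting ER calcium (uM).
#' @param C_C0 resting cytosolic calcium (nM).
#' @param D_C cytosolic calcium diffusion coefficient (um^2/s).
#' @param D_S ER calcium diffusion coefficient (um^2/s); 10 by default, 110
#'   for the fast-ER-diffusion variant.
#' @param serca_Vmax maximal molar pumping rate per SERCA (mol/s).
#' @param serca_KC cytosolic half-saturation constant (uM).
#' @return An object of class `flux_params`.
#' @export
flux_params <- function(I_ORAI = 2.1e-15, I_IP3R = 6.4e-14,
                        C_S0 = 400, C_C0 = 30,
                        D_C = 220, D_S = 10,
                        serca_Vmax = 2e-20, serca_KC = 50) {
  vals <- c(I_ORAI = I_ORAI, I_IP3R = I_IP3R, C_S0 = C_S0, C_C0 = C_C0,
            D_C = D_C, D_S = D_S, serca_Vmax = serca_Vmax, serca_KC = serca_KC)
  if (any(vals <= 0))
    invalid_argument("all currents, concentrations and diffusivities must be > 0")
  p <- list(I_ORAI = I_ORAI, I_IP3R = I_IP3R,
            C_S0 = C_S0, C_C0 = C_C0, D_C = D_C, D_S = D_S,
            F = socesim_constants$faraday, z = 2,
            serca_Vmax = serca_Vmax, serca_KC = serca_KC)
  # rest-equilibrium constraint (concentrations compared in common units)
  p$serca_KS <- serca_KC * (C_S0 * 1e3) / C_C0  # uM * (uM->nM) / nM -> uM
  # SI versions used by the solver
  p$cs0 <- uM_to_molm3(C_S0)
  p$cc0 <- nM_to_molm3(C_C0)
  p$dc <- D_C * UM2_S
  p$ds <- D_S * UM2_S
  structure(p, class = "flux_params")
}

#' ORAI1 molar rate
#'
#' Total molar rate of calcium entry through one ORAI1 channel open at
#' fraction `f`: `f * I_ORAI / (z * F)` (mol/s), directed into the cytosol.
#' Dividing by the pore area gives the flux density applied on the patch.
#'
#' @param f open fraction in \[0, 1\].
#' @param params a [flux_params()].
#' @return molar rate (mol/s).
#' @export
orai_molar_rate <- function(f, params) {
  if (any(f < 0 | f > 1)) invalid_argument("f must lie in [0, 1]")
  f * params$I_ORAI / (params$z * params$F)
}

#' Calcium ions entering through ORAI1 channels over a time window
#'
#' @param n_channels number of simultaneously open channels.
#' @param f open fraction.
#' @param duration opening duration (s).
#' @param params a [flux_params()].
#' @return expected number of ions.
#' @examples
#' ions_entered(5, 0.21, 0.044)  # ~303 ions
#' @export
ions_entered <- function(n_channels, f, duration, params = flux_params()) {
  if (duration < 0) invalid_argument("duration must be >= 0")
  n_channels * orai_molar_rate(f, params) * duration * socesim_constants$avogadro
}

#' IP3R molar rate
#'
#' Total molar rate through one IP3 receptor, the unitary rate
#' `I_IP3R / (z * F)` scaled by the actual trans-pore concentration gradient
#' relative to the resting gradient:
#' `rate = I_IP3R/(z F) * (cs_mouth - cc_mouth) / (C_S0 - C_C0)`.
#' Positive into the cytosol when the luminal mouth concentration exceeds the
#' cytosolic one.
#'
#' @param cs_mouth luminal (ER-side) mouth concentration (uM).
#' @param cc_mouth cytosolic mouth concentration (uM).
#' @param params a [flux_params()].
#' @return molar rate (mol/s).
#' @export
ip3r_molar_rate <- function(cs_mouth, cc_mouth, params) {
  if (any(cs_mouth < 0) || any(cc_mouth < 0))
    invalid_argument("mouth concentrations must be >= 0")
  grad0 <- params$cs0 - params$cc0
  params$I_IP3R / (params$z * params$F) *
    (uM_to_molm3(cs_mouth) - uM_to_molm3(cc_mouth)) / grad0
}

#' SERCA pump molar rate
#'
#' Bidirectional second-order Hill pump:
#' `rate = Vmax * ((cc/KC)^2 - (cs/KS)^2) / (1 + (cc/KC)^2 + (cs/KS)^2)`,
#' positive when pumping cytosol to ER.  With the rest-equilibrium constraint
#' on `KS` the net rate is exactly zero at resting concentrations, the rate
#' is strictly increasing in cytosolic calcium, strictly decreasing in
#' luminal calcium, and bounded by `+/- Vmax`.
#'
#' @param cc_mouth cytosolic mouth concentration (uM).
#' @param cs_mouth luminal mouth concentration (uM).
#' @param params a [flux_params()].
#' @return molar rate (mol/s), positive cytosol -> ER.
#' @export
serca_molar_rate <- function(cc_mouth, cs_mouth, params) {
  if (any(cc_mouth < 0) || any(cs_mouth < 0))
    invalid_argument("mouth concentrations must be >= 0")
  a <- (cc_mouth / params$serca_KC)^2
  b <- (cs_mouth / params$serca_KS)^2
  params$serca_Vmax * (a - b) / (1 + a + b)
}
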