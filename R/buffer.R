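# Buffer speciation and screening: total solute concentrations at a stated
# pH -> speciated ions, ionic strength I = 1/2 sum(c_i z_i^2), Debye length,
# and ideal (van 't Hoff) osmolarity. Ideal-solution throughout: no activity
# coefficients, no ion pairing.

#' Declare one solute of a buffer recipe
#'
#' Three kinds are supported:
#' * **weak acid/base** — give the `pkas` of its dissociable protons and
#'   `z_max` (charge of the fully protonated form, e.g. 0 for H3PO4, 0 for
#'   acetic acid); it is distributed across protonation states at the recipe
#'   pH. `counter_cations` counts monovalent cations delivered per formula
#'   unit when the solute is added as a salt (2 for Na2HPO4, 1 for KH2PO4 or
#'   sodium acetate).
#' * **strong electrolyte** — give `ions` as a named numeric vector of
#'   charges with attribute-free stoichiometry in `stoich` (e.g. NaCl:
#'   `ions = c(Na = 1, Cl = -1)`).
#' * **nonionic** — `nonionic = TRUE`; contributes to osmolarity only.
#'
#' @param name label.
#' @param conc_M total concentration, mol/L.
#' @param pkas numeric vector of pKa values (weak acid kind).
#' @param z_max charge of the fully protonated species.
#' @param counter_cations monovalent cations co-delivered per formula unit.
#' @param ions named charges for a strong electrolyte.
#' @param stoich stoichiometric counts matching `ions`.
#' @param nonionic logical.
#' @return an object of class `solute`.
#' @export
solute <- function(name, conc_M, pkas = NULL, z_max = 0, counter_cations = 0,
                   ions = NULL, stoich = NULL, nonionic = FALSE) {
  if (conc_M < 0) stop_input("concentration must be >= 0")
  kind <- if (nonionic) "nonionic" else if (!is.null(pkas)) "weak" else "strong"
  if (kind == "strong" && is.null(ions))
    stop_input("solute '", name, "': give pkas, ions, or nonionic = TRUE")
  if (kind == "strong" && is.null(stoich)) stoich <- rep(1, length(ions))
  structure(list(name = name, conc_M = conc_M, kind = kind, pkas = sort(pkas),
                 z_max = z_max, counter_cations = counter_cations,
                 ions = ions, stoich = stoich),
            class = "solute")
}

#' Assemble a buffer recipe
#'
#' @param name label for reports.
#' @param solutes list of [solute()] objects.
#' @param pH target pH the buffer is titrated to.
#' @param temperature_K temperature, K.
#' @return an object of class `buffer_recipe`.
#' @export
buffer_recipe <- function(name, solutes, pH, temperature_K = 298.15) {
  if (pH < 0 || pH > 14) stop_input("pH must lie in [0, 14]")
  if (!length(solutes) || !all(vapply(solutes, inherits, TRUE, "solute")))
    stop_input("`solutes` must be a list of solute() objects")
  structure(list(name = name, solutes = solutes, pH = pH,
                 temperature_K = temperature_K),
            class = "buffer_recipe")
}

# fractional populations of the protonation states of an n-protic acid at pH
# (state j = number of protons released; charges z_max - j)
.protonation_fractions <- function(pkas, pH) {
  n <- length(pkas)
  # cumulative log10 of [state j]/[state 0] = sum_{i<=j} (pH - pKa_i)
  logf <- c(0, cumsum(pH - pkas))
  w <- 10^(logf - max(logf))
  w / sum(w)
}

#' Speciate a buffer recipe into its ionic state
#'
#' Distributes each weak acid/base across protonation states by
#' Henderson-Hasselbalch at the recipe pH, adds strong-electrolyte ions and
#' H+/OH- at the stated pH, then balances residual charge with monovalent
#' counter-ions (Na+ or Cl-, as needed) — the titrant implied by "buffer at
#' pH x". Ionic strength is `I = 1/2 sum(c_i z_i^2)`; osmolarity is the
#' ideal particle sum over ions and nonionic solutes.
#'
#' @param recipe a [buffer_recipe()] (or preset name, see
#'   [buffer_preset()]).
#' @return object of class `ionic_state`: `ions` data.frame
#'   (`species, z, conc_M`), `I_M`, `debye_nm`, `osmolarity_mOsm`,
#'   `net_charge_M` (residual after balancing; < 1e-9 by construction).
#' @export
speciate <- function(recipe) {
  if (is.character(recipe)) recipe <- buffer_preset(recipe)
  stopifnot(inherits(recipe, "buffer_recipe"))
  pH <- recipe$pH
  species <- character(0); z <- numeric(0); conc <- numeric(0)
  osmo_nonionic <- 0
  add <- function(s, zz, cc) {
    species <<- c(species, s); z <<- c(z, zz); conc <<- c(conc, cc)
  }
  add("H+", 1, 10^(-pH))
  add("OH-", -1, 10^(-(14 - pH)))
  for (sol in recipe$solutes) {
    if (sol$conc_M == 0) next
    if (sol$kind == "nonionic") {
      osmo_nonionic <- osmo_nonionic + sol$conc_M
    } else if (sol$kind == "strong") {
      for (i in seq_along(sol$ions))
        add(names(sol$ions)[i] %||% sprintf("%s_ion%d", sol$name, i),
            sol$ions[[i]], sol$conc_M * sol$stoich[[i]])
    } else {
      fr <- .protonation_fractions(sol$pkas, pH)
      zs <- sol$z_max - (seq_along(fr) - 1)
      for (j in seq_along(fr))
        if (fr[j] > 1e-12)
          add(sprintf("%s[z=%+d]", sol$name, zs[j]), zs[j], sol$conc_M * fr[j])
      if (sol$counter_cations > 0)
        add("Na+", 1, sol$conc_M * sol$counter_cations)
    }
  }
  resid <- sum(conc * z)
  if (resid > 1e-15) add("Cl-", -1, resid) else if (resid < -1e-15) add("Na+", 1, -resid)
  ions <- data.frame(species = species, z = z, conc_M = conc,
                     stringsAsFactors = FALSE)
  # merge duplicate species rows
  agg <- stats::aggregate(conc_M ~ species + z, data = ions, FUN = sum)
  I <- 0.5 * sum(agg$conc_M * agg$z^2)
  osmo <- (sum(agg$conc_M) + osmo_nonionic) * 1000
  structure(list(recipe_name = recipe$name, pH = pH,
                 temperature_K = recipe$temperature_K,
                 ions = agg[order(-agg$conc_M), ],
                 I_M = I,
                 debye_nm = debye_length(I, recipe$temperature_K),
                 osmolarity_mOsm = osmo,
                 net_charge_M = sum(agg$conc_M * agg$z)),
            class = "ionic_state")
}

#' @export
print.ionic_state <- function(x, ...) {
  cat(sprintf("<ionic_state> %s (pH %.1f): I = %.4g M, kappa^-1 = %s nm, %.0f mOsm/L\n",
              x$recipe_name, x$pH, x$I_M,
              if (is.finite(x$debye_nm)) sprintf("%.3g", x$debye_nm) else "Inf",
              x$osmolarity_mOsm))
  invisible(x)
}

#' Debye screening length of an electrolyte
#'
#' `kappa^-1 = sqrt(eps_r eps_0 k_B T / (2 N_A e^2 I * 1e3))`, returned in
#' nanometres. At 298.15 K in water this is approximately `0.304 / sqrt(I)`
#' nm with I in mol/L.
#'
#' @param I ionic strength, mol/L (or an `ionic_state`).
#' @param temperature_K temperature, K.
#' @param eps_r relative permittivity of the solvent (78.5 for water near
#'   298 K).
#' @return Debye length in nm; `Inf` (with a warning) at I = 0.
#' @export
debye_length <- function(I, temperature_K = 298.15, eps_r = 78.5) {
  if (inherits(I, "ionic_state")) I <- I$I_M
  if (I < 0) stop_input("ionic strength must be >= 0")
  if (I == 0) {
    warning("I = 0: unscreened (infinite Debye length)", call. = FALSE)
    return(Inf)
  }
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  e <- 1.602176634e-19       # C
  NA_ <- 6.02214076e23       # 1/mol
  kappa_inv_m <- sqrt(eps_r * eps0 * kB * temperature_K /
                        (2 * NA_ * e^2 * I * 1e3))
  kappa_inv_m * 1e9
}

#' Screened-Coulomb repulsion index for like-charged filament subunits
#'
#' An *interpretive* dimensionless ranking tool, not a model stated in the
#' source experiments: the Yukawa pair-energy scale
#' `Z^2 exp(-d / kappa^-1) / d` (Bjerrum-normalized units) for subunits of
#' net charge Z at spacing d in a medium of Debye length kappa^-1. It grows
#' with |Z| squared, falls with spacing, and grows as screening weakens —
#' the qualitative stability ordering of charged-filament media.
#'
#' @param charge_per_subunit net charge Z, elementary units.
#' @param subunit_spacing_nm characteristic charge spacing along the
#'   filament, nm.
#' @param debye_nm Debye length (or an `ionic_state`).
#' @return dimensionless index (label `"interpretive"` attached as
#'   attribute `provenance`).
#' @export
repulsion_index <- function(charge_per_subunit, subunit_spacing_nm, debye_nm) {
  if (inherits(debye_nm, "ionic_state")) debye_nm <- debye_nm$debye_nm
  if (subunit_spacing_nm <= 0) stop_input("subunit spacing must be > 0")
  idx <- charge_per_subunit^2 *
    exp(-subunit_spacing_nm / debye_nm) / subunit_spacing_nm
  attr(idx, "provenance") <- "interpretive"
  idx
}

#' Built-in buffer presets
#'
#' The experimental media of the low-ionic-strength vimentin assays plus
#' reference solutions:
#' `"phosphate5_pH7.3_glucose350"` (5 mM sodium phosphate pH 7.3 + 350 mM
#' glucose — high osmolarity, low ionic strength), `"dpbs"` (no-Ca/Mg DPBS,
#' pH 7.3), `"acetate5_pH5.0"`, `"capso5_pH9.0"`, `"capso5_pH10.0"`,
#' `"nacl150"` (150 mM saline) and `"water"`.
#'
#' @param name preset identifier.
#' @return a [buffer_recipe()].
#' @export
buffer_preset <- function(name) {
  ph_pkas <- c(2.15, 7.20, 12.35)
  presets <- list(
    "phosphate5_pH7.3_glucose350" = function() buffer_recipe(
      "phosphate5_pH7.3_glucose350",
      list(solute("phosphate", 5e-3, pkas = ph_pkas, z_max = 0,
                  counter_cations = 1),
           solute("glucose", 0.350, nonionic = TRUE)),
      pH = 7.3),
    "phosphate5_pH7.3" = function() buffer_recipe(
      "phosphate5_pH7.3",
      list(solute("phosphate", 5e-3, pkas = ph_pkas, z_max = 0,
                  counter_cations = 1)),
      pH = 7.3),
    "dpbs" = function() buffer_recipe(
      "dpbs",
      list(solute("NaCl", 0.1379, ions = c("Na+" = 1, "Cl-" = -1)),
           solute("KCl", 2.7e-3, ions = c("K+" = 1, "Cl-" = -1)),
           solute("phosphate", 8.1e-3, pkas = ph_pkas, z_max = 0,
                  counter_cations = 2),   # Na2HPO4
           solute("phosphate", 1.5e-3, pkas = ph_pkas, z_max = 0,
                  counter_cations = 1)),  # KH2PO4 (K+ ~ Na+ here)
      pH = 7.3),
    "acetate5_pH5.0" = function() buffer_recipe(
      "acetate5_pH5.0",
      list(solute("acetate", 5e-3, pkas = 4.76, z_max = 0,
                  counter_cations = 1)),
      pH = 5.0),
    "capso5_pH9.0" = function() buffer_recipe(
      "capso5_pH9.0",
      list(solute("CAPSO", 5e-3, pkas = 9.6, z_max = 0, counter_cations = 1)),
      pH = 9.0),
    "capso5_pH10.0" = function() buffer_recipe(
      "capso5_pH10.0",
      list(solute("CAPSO", 5e-3, pkas = 9.6, z_max = 0, counter_cations = 1)),
      pH = 10.0),
    "nacl150" = function() buffer_recipe(
      "nacl150", list(solute("NaCl", 0.150, ions = c("Na+" = 1, "Cl-" = -1))),
      pH = 7.0),
    "water" = function() buffer_recipe(
      "water", list(solute("nothing", 0, nonionic = TRUE)), pH = 7.0))
  if (!name %in% names(presets))
    stop_input("unknown buffer preset '", name, "'; available: ",
               paste(names(presets), collapse = ", "))
  presets[[name]]()
}
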