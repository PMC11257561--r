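# Assembly-state inference: diffusion coefficient -> average oligomer size.
#
# For compact globular species, D scales inversely with the cube root of
# molecular weight with little dependence on shape (Stokes-Einstein with
# volume ~ mass). A measured D relative to a monomeric reference of known
# mass therefore yields the mass of the diffusing species, and dividing by
# the subunit mass yields the average oligomer size.

#' Average oligomer size from a measured diffusion coefficient
#'
#' Inverts the cube-root scaling `D ~ M^(-1/3)`: the diffusing species mass
#' is `M = mw_reference * (D_reference / D_measured)^3`. Under the
#' `all-fusions` composition assumption every subunit is a tagged fusion, so
#' `n_subunits = M / mw_construct` and the subunit count equals the
#' filament-protein count. Under `one-tag` a single tagged construct diffuses
#' with untagged protein, so `n_vimentin = (M - mw_reference) / mw_vimentin`.
#'
#' @param D_measured measured diffusion coefficient, um^2/s.
#' @param D_reference diffusion coefficient of the monomeric reference (the
#'   free fluorescent protein), um^2/s. May also be supplied as a ratio via
#'   equal units; only the ratio `D_reference / D_measured` enters.
#' @param mw_reference reference (fluorescent protein) mass, kDa.
#' @param mw_construct tagged-construct (fusion) mass, kDa.
#' @param mw_vimentin untagged filament-protein mass, kDa (used by
#'   `one-tag`).
#' @param composition `"all-fusions"` (default) or `"one-tag"`.
#' @return object of class `oligomer_estimate` with fields `n_subunits`,
#'   `n_vimentin`, `n_vimentin_rounded10` (headline convenience value,
#'   nearest multiple of ten), `species_mass_kDa`, the echoed inputs and the
#'   `assumption_label`.
#' @export
oligomer_size_from_D <- function(D_measured, D_reference,
                                 mw_reference = 27, mw_construct = 81,
                                 mw_vimentin = 54,
                                 composition = c("all-fusions", "one-tag")) {
  composition <- match.arg(composition)
  vals <- c(D_measured, D_reference, mw_reference, mw_construct, mw_vimentin)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_input("all diffusivities and masses must be positive finite numbers")
  if (D_measured > D_reference)
    warning("D_measured exceeds D_reference: inferred size < 1 subunit",
            call. = FALSE)
  M <- mw_reference * (D_reference / D_measured)^3
  if (composition == "all-fusions") {
    n_sub <- M / mw_construct
    n_vim <- n_sub
  } else {
    n_sub <- 1 + (M - mw_reference) / mw_vimentin  # one tagged + untagged
    n_vim <- (M - mw_reference) / mw_vimentin
  }
  structure(list(n_subunits = n_sub, n_vimentin = n_vim,
                 n_vimentin_rounded10 = 10 * round(n_vim / 10),
                 species_mass_kDa = M,
                 assumption_label = composition,
                 inputs = list(D_measured = D_measured,
                               D_reference = D_reference,
                               mw_reference = mw_reference,
                               mw_construct = mw_construct,
                               mw_vimentin = mw_vimentin)),
            class = "oligomer_estimate")
}

#' @export
print.oligomer_estimate <- function(x, ...) {
  cat(sprintf(paste0("<oligomer_estimate> species mass %.1f kDa -> %.2f subunits",
                     " (~%d filament proteins, '%s' assumption)\n"),
              x$species_mass_kDa, x$n_subunits,
              as.integer(x$n_vimentin_rounded10), x$assumption_label))
  invisible(x)
}

#' Predicted diffusion coefficient for an n-mer of tagged constructs
#'
#' The forward direction of the same cube-root mass scaling:
#' `D = D_reference * (mw_reference / (n * mw_construct))^(1/3)`.
#'
#' @param n number of construct subunits (>= 1).
#' @inheritParams oligomer_size_from_D
#' @return predicted D, um^2/s.
#' @export
predicted_D_for_oligomer <- function(n, mw_construct = 81, mw_reference = 27,
                                     D_reference) {
  if (any(n < 1)) stop_input("`n` must be >= 1")
  if (any(c(mw_construct, mw_reference, D_reference) <= 0))
    stop_input("masses and D_reference must be positive")
  D_reference * (mw_reference / (n * mw_construct))^(1 / 3)
}

#' Classify map bins as filament-bound or dispersed
#'
#' Thresholds the fitted diffusivity map: bins with `D_hat < D_threshold`
#' are labeled `bound`, the rest `dispersed`. The default threshold 3
#' um^2/s is the log-scale midpoint between the filament-state (~1.5) and
#' dispersed-state (~6.7) regimes.
#'
#' @param map a `diffusivity_map`.
#' @param D_threshold classification boundary, um^2/s.
#' @return list of class `assembly_classification`: character matrix
#'   `labels` (NA where masked), `bound_fraction` of unmasked bins.
#' @export
classify_assembly_state <- function(map, D_threshold = 3.0) {
  stopifnot(inherits(map, "diffusivity_map"))
  if (all(map$masked)) stop_input("fully masked map: nothing to classify")
  labels <- matrix(NA_character_, nrow(map$D_hat), ncol(map$D_hat))
  labels[!map$masked] <- ifelse(map$D_hat[!map$masked] < D_threshold,
                                "bound", "dispersed")
  structure(list(labels = labels,
                 bound_fraction = mean(labels[!map$masked] == "bound"),
                 D_threshold = D_threshold),
            class = "assembly_classification")
}
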