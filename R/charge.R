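# Sequence-based protein electrostatics: molecular weight, net charge versus
# pH (Henderson-Hasselbalch per ionizable group), isoelectric point, and
# fusion-construct charge arithmetic.

# Average (isotope-abundance) residue masses, Da, for residues in a peptide
# chain (monomer mass minus one water); one water is added back per chain.
.residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01528

# pKa presets. "emboss" is the EMBOSS iep default table. "protcalc" carries
# the constants documented for Protein Calculator v3.4
# (protcalc.sourceforge.net), the sequence-only calculator conventionally
# used for intermediate-filament charge curves.
.pka_presets <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  protcalc = c(Nterm = 8.0, Cterm = 3.1, C = 8.5, D = 4.4, E = 4.4,
               H = 6.5, K = 10.0, R = 12.0, Y = 10.0))

.acidic_groups <- c("D", "E", "C", "Y", "Cterm")
.basic_groups <- c("K", "R", "H", "Nterm")

#' pKa preset tables for net-charge calculation
#'
#' @param name `"emboss"` (EMBOSS iep defaults) or `"protcalc"`
#'   (Protein Calculator v3.4-compatible constants). A named numeric vector
#'   with entries `Nterm, Cterm, C, D, E, H, K, R, Y` may be supplied
#'   directly anywhere a preset name is accepted.
#' @return named numeric vector of pKa values.
#' @export
pka_set <- function(name = "protcalc") {
  if (is.numeric(name)) {
    need <- names(.pka_presets$emboss)
    if (!all(need %in% names(name)))
      stop_input("custom pKa set must name all of: ", paste(need, collapse = ", "))
    if (any(name <= 0 | name >= 14)) stop_input("pKa values must lie in (0, 14)")
    return(name[need])
  }
  if (!name %in% names(.pka_presets))
    stop_input("unknown pKa preset '", name, "'; available: ",
               paste(names(.pka_presets), collapse = ", "))
  .pka_presets[[name]]
}

.clean_sequence <- function(sequence, permissive = FALSE) {
  s <- toupper(gsub("[[:space:]*]", "", sequence))
  if (!nzchar(s)) stop_input("empty protein sequence")
  letters_seen <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(letters_seen), names(.residue_mass))
  if (length(bad)) {
    if (!permissive)
      stop_input("non-standard residue letter(s): ", paste(bad, collapse = ", "),
                 " (set permissive = TRUE to skip them)")
    message("skipping ", sum(letters_seen %in% bad),
            " non-standard residue(s): ", paste(bad, collapse = ", "))
    letters_seen <- letters_seen[!letters_seen %in% bad]
  }
  letters_seen
}

#' Read protein sequences from a FASTA file
#'
#' Minimal single/multi-record FASTA reader for plain-text protein files:
#' header lines start with `>`, sequence lines are concatenated, whitespace
#' is dropped. Residue letters are validated against the 20 standard amino
#' acids.
#'
#' @param path FASTA file path.
#' @param permissive skip (with a message) rather than reject non-standard
#'   residue letters.
#' @return named character vector of sequences; names are the first word of
#'   each header.
#' @export
read_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L]) stop_input("not a FASTA file: ", path)
  rec <- cumsum(hdr)
  headers <- sub("^>\\s*", "", lines[hdr])
  names_out <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste0, "", collapse = "")
  if (length(seqs) != length(names_out) || any(!nzchar(seqs)))
    stop_input("FASTA record(s) without sequence in ", path)
  seqs <- vapply(seqs, function(s)
    paste0(.clean_sequence(s, permissive = permissive), collapse = ""), "")
  setNames(unname(seqs), names_out)
}

#' Residue composition and mass bookkeeping for one protein chain
#'
#' @param sequence one-letter amino-acid sequence (string).
#' @param name optional label.
#' @param permissive skip non-standard letters instead of erroring.
#' @return object of class `protein_species`: `name`, `sequence`, `length`,
#'   `counts` (all 20 residues), `mw_kDa`.
#' @export
protein_species <- function(sequence, name = "protein", permissive = FALSE) {
  letters_seen <- .clean_sequence(sequence, permissive = permissive)
  counts <- table(factor(letters_seen, levels = names(.residue_mass)))
  structure(list(name = name,
                 sequence = paste0(letters_seen, collapse = ""),
                 length = length(letters_seen),
                 counts = setNames(as.integer(counts), names(.residue_mass)),
                 mw_kDa = (sum(.residue_mass[letters_seen]) + .water_mass) / 1000),
            class = "protein_species")
}

#' @export
print.protein_species <- function(x, ...) {
  cat(sprintf("<protein_species> %s: %d aa, %.1f kDa (D+E = %d, K+R = %d)\n",
              x$name, x$length, x$mw_kDa,
              x$counts[["D"]] + x$counts[["E"]],
              x$counts[["K"]] + x$counts[["R"]]))
  invisible(x)
}

#' Molecular weight of a protein chain
#'
#' Sum of average residue masses plus one water, in kDa.
#'
#' @inheritParams protein_species
#' @return molecular weight, kDa.
#' @export
molecular_weight <- function(sequence, permissive = FALSE) {
  protein_species(sequence, permissive = permissive)$mw_kDa
}

# Henderson-Hasselbalch group charges at a given pH.
# basic:  +1 / (1 + 10^(pH - pKa));  acidic:  -1 / (1 + 10^(pKa - pH))
.group_charge <- function(group, n, pH, pka) {
  if (n == 0) return(0)
  if (group %in% .basic_groups) {
    n / (1 + 10^(pH - pka[[group]]))
  } else {
    -n / (1 + 10^(pka[[group]] - pH))
  }
}

#' Sequence-based net charge at a given pH
#'
#' Sums Henderson-Hasselbalch fractional charges over the ionizable side
#' chains (D, E, C, Y acidic; K, R, H basic) and, unless suppressed, the two
#' chain termini. This is the sequence-only model behind conventional
#' protein charge-versus-pH curves: no structural pKa shifts, no
#' post-translational modifications.
#'
#' @inheritParams protein_species
#' @param pH a value (or vector) in `[0, 14]`.
#' @param pka preset name or named pKa vector (see [pka_set()]).
#' @param termini `"both"` to count the N- and C-terminus, `"none"` for an
#'   internal segment (e.g. a linker inside a fusion).
#' @param include_CY count cysteine and tyrosine as acidic groups (the
#'   convention of the supported calculators); set `FALSE` to drop them.
#' @return net charge in elementary units (vectorized over `pH`).
#' @export
net_charge <- function(sequence, pH = 7.3, pka = "protcalc",
                       termini = c("both", "none"), include_CY = TRUE,
                       permissive = FALSE) {
  termini <- match.arg(termini)
  if (any(pH < 0 | pH > 14)) stop_input("pH must lie in [0, 14]")
  pka <- pka_set(pka)
  sp <- if (inherits(sequence, "protein_species")) sequence
        else protein_species(sequence, permissive = permissive)
  groups <- c("D", "E", "K", "R", "H", if (include_CY) c("C", "Y"))
  vapply(pH, function(p) {
    z <- sum(vapply(groups, function(g)
      .group_charge(g, sp$counts[[g]], p, pka), 0))
    if (termini == "both")
      z <- z + .group_charge("Nterm", 1L, p, pka) +
        .group_charge("Cterm", 1L, p, pka)
    z
  }, 0)
}

#' Net charge versus pH curve with isoelectric point
#'
#' Evaluates [net_charge()] on a pH grid and locates the isoelectric point
#' by bisection to 1e-4 pH units. The curve is strictly decreasing in pH, so
#' the zero crossing is unique whenever the sequence carries both acidic and
#' basic groups.
#'
#' @inheritParams net_charge
#' @param pH_lo,pH_hi,step grid limits and spacing.
#' @return object of class `charge_curve`: data.frame `curve` (`pH`, `Z`),
#'   `pI` (NA with `pI_defined = FALSE` when no crossing exists), inputs.
#' @export
charge_curve <- function(sequence, pH_lo = 2, pH_hi = 13, step = 0.1,
                         pka = "protcalc", include_CY = TRUE,
                         permissive = FALSE) {
  if (pH_lo >= pH_hi) stop_input("pH_lo must be < pH_hi")
  sp <- if (inherits(sequence, "protein_species")) sequence
        else protein_species(sequence, permissive = permissive)
  grid <- seq(pH_lo, pH_hi, by = step)
  Z <- net_charge(sp, grid, pka = pka, include_CY = include_CY)
  f <- function(p) net_charge(sp, p, pka = pka, include_CY = include_CY)
  pI <- NA_real_; defined <- FALSE
  z0 <- f(0); z14 <- f(14)
  if (z0 > 0 && z14 < 0) {
    pI <- uniroot(f, c(0, 14), tol = 1e-4)$root
    defined <- TRUE
  }
  structure(list(curve = data.frame(pH = grid, Z = Z),
                 pI = pI, pI_defined = defined,
                 name = sp$name, pka = pka_set(pka)),
            class = "charge_curve")
}

#' @export
print.charge_curve <- function(x, ...) {
  cat(sprintf("<charge_curve> %s: Z(%.1f) = %.2f .. Z(%.1f) = %.2f; pI = %s\n",
              x$name, x$curve$pH[1], x$curve$Z[1],
              x$curve$pH[nrow(x$curve)], x$curve$Z[nrow(x$curve)],
              if (x$pI_defined) sprintf("%.2f", x$pI) else "undefined"))
  invisible(x)
}

#' Plot a charge curve
#' @param x a `charge_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.charge_curve <- function(x, ...) {
  plot(x$curve$pH, x$curve$Z, type = "l", lwd = 2, col = "firebrick",
       xlab = "pH", ylab = "net charge (e)", main = x$name, ...)
  abline(h = 0, lty = 3)
  if (x$pI_defined) {
    points(x$pI, 0, pch = 19)
    text(x$pI, 0, sprintf("pI = %.2f", x$pI), pos = 4, cex = 0.8)
  }
  invisible(x)
}

#' Net charge of a fusion construct
#'
#' Components are assembled into a single chain: character components are
#' concatenated (internal junctions contribute no extra termini; the
#' N-terminus of the first and the C-terminus of the last residue are
#' counted once) and numeric components pass through as fixed charges (e.g.
#' a `-2` per phosphosite, or a linker of stated formal charge).
#'
#' @param components list whose elements are sequences (character) and/or
#'   fixed charges (numeric).
#' @inheritParams net_charge
#' @return net charge in elementary units.
#' @export
fusion_charge <- function(components, pH = 7.3, pka = "protcalc",
                          include_CY = TRUE, permissive = FALSE) {
  if (!is.list(components) || length(components) == 0L)
    stop_input("`components` must be a non-empty list")
  is_seq <- vapply(components, is.character, TRUE)
  is_fix <- vapply(components, is.numeric, TRUE)
  if (!all(is_seq | is_fix))
    stop_input("components must be sequences (character) or fixed charges (numeric)")
  z <- sum(unlist(components[is_fix]), 0)
  if (any(is_seq)) {
    chain <- paste0(unlist(components[is_seq]), collapse = "")
    z <- z + net_charge(chain, pH, pka = pka, termini = "both",
                        include_CY = include_CY, permissive = permissive)
  }
  z
}

#' @importFrom graphics abline points
NULL
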