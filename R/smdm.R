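# Spatial binning and maximum-likelihood fitting of SMdM displacements.
#
# Each spatial bin's displacement magnitudes r are fit to the SMdM diffusion
# model: a single-population 2D Brownian step observed with localization
# error,
#     P(r | D) = (r / s^2) * exp(-r^2 / (2 s^2)),   s^2 = 2 D dt + 2 sigma_loc^2
# (a Rayleigh distribution in r), optionally mixed with a uniform-in-area
# background P_bg(r) = 2 r / R_cap^2 at weight phi.  D-hat (and phi-hat if
# enabled) maximize the likelihood.

#' Spatial bin lattice for displacement maps
#'
#' Half-open bins `[lo, hi)`, 0-based row-major indexing in the descriptor,
#' y increasing downward (image convention). Origins falling exactly on a
#' boundary go to the higher-index bin.
#'
#' @param origin `c(x, y)` of the lattice corner, um.
#' @param bin_size bin edge, um.
#' @param n_rows,n_cols lattice dimensions.
#' @return an object of class `bin_lattice`.
#' @export
bin_lattice <- function(origin = c(0, 0), bin_size = 0.4, n_rows, n_cols) {
  if (bin_size <= 0) stop_input("`bin_size` must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows <= 0L || n_cols <= 0L) stop_input("lattice dimensions must be positive")
  structure(list(origin = as.numeric(origin), bin_size = bin_size,
                 n_rows = n_rows, n_cols = n_cols),
            class = "bin_lattice")
}

#' Lattice covering a diffusivity field, bin-for-bin
#' @param field a `diffusivity_field`.
#' @return a [bin_lattice()] congruent with the field grid.
#' @export
lattice_from_field <- function(field) {
  bin_lattice(origin = field$origin, bin_size = field$bin_size,
              n_rows = nrow(field$D), n_cols = ncol(field$D))
}

#' Assign displacement records to lattice bins by their origin
#'
#' @param table data.frame with at least `x0_um`, `y0_um` (the
#'   [simulate_displacements()] schema).
#' @param lattice a [bin_lattice()].
#' @return list: `row`, `col` (1-based indices, NA when out of field),
#'   `bin_id` (linear index), `n_out_of_field`. Per-bin counts plus the
#'   out-of-field count always sum to `nrow(table)`.
#' @export
bin_displacements <- function(table, lattice) {
  stopifnot(inherits(lattice, "bin_lattice"))
  req <- c("x0_um", "y0_um")
  if (!all(req %in% names(table)))
    stop_input("table must have columns x0_um, y0_um")
  if (nrow(table) == 0L) {
    warning("empty displacement table: empty binning", call. = FALSE)
    return(list(row = integer(0), col = integer(0), bin_id = integer(0),
                n_out_of_field = 0L, lattice = lattice))
  }
  col <- 1L + floor((table$x0_um - lattice$origin[1]) / lattice$bin_size)
  row <- 1L + floor((table$y0_um - lattice$origin[2]) / lattice$bin_size)
  inside <- row >= 1L & row <= lattice$n_rows & col >= 1L & col <= lattice$n_cols
  row[!inside] <- NA_integer_; col[!inside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col),
       bin_id = as.integer((col - 1L) * lattice$n_rows + row),
       n_out_of_field = sum(!inside), lattice = lattice)
}

# Negative log-likelihood of magnitudes r under the mixture model. Returns a
# large finite penalty (not Inf) outside the support so that L-BFGS-B always
# sees usable values.
.smdm_nll <- function(D, phi, r, dt, sigma_loc, R_cap) {
  s2 <- 2 * D * dt + 2 * sigma_loc^2
  if (s2 <= 0) return(1e12)
  f_sig <- (r / s2) * exp(-r^2 / (2 * s2))
  if (phi > 0) {
    f <- (1 - phi) * f_sig + phi * 2 * r / R_cap^2
  } else {
    f <- f_sig
  }
  if (any(f <= 0) || any(!is.finite(f))) return(1e12)
  -sum(log(f))
}

#' Fit the SMdM diffusion model to one bin's displacement magnitudes
#'
#' Maximum-likelihood estimate of the local diffusion coefficient from a set
#' of displacement magnitudes, under the single-population model (default)
#' or mixed with a uniform-in-area background at weight `phi`. With no
#' background and `sigma_loc = 0`, the MLE has the closed form
#' `sum(r^2) / (4 N dt)`; the numeric optimizer reproduces it to high
#' precision (a Newton polish on the score is applied after bracketing).
#'
#' @param r displacement magnitudes, um (all in `[0, R_cap]`).
#' @param settings an [acquisition_settings()] (supplies `dt`, `sigma_loc`,
#'   `capture_radius`).
#' @param background if `TRUE`, fit the background weight `phi` jointly.
#' @param n_min minimum number of displacements required; below it the
#'   result is masked (`converged = FALSE`, `D_hat = NA`), not an error.
#' @param tol convergence tolerance on D, um^2/s.
#' @return an object of class `smdm_fit`: `D_hat`, `phi`, `n_used`,
#'   `log_likelihood`, `converged`.
#' @export
fit_diffusivity <- function(r, settings, background = FALSE, n_min = 10L,
                            tol = 1e-8) {
  stopifnot(inherits(settings, "acquisition_settings"))
  if (length(r) && (!is.numeric(r) || any(!is.finite(r))))
    stop_input("displacement magnitudes must be finite numbers")
  if (any(r < 0)) stop_input("displacement magnitudes must be >= 0")
  dt <- settings$dt; sig <- settings$sigma_loc; R_cap <- settings$capture_radius
  if (length(r) < n_min) {
    return(structure(list(D_hat = NA_real_, phi = NA_real_,
                          n_used = length(r), log_likelihood = NA_real_,
                          converged = FALSE), class = "smdm_fit"))
  }
  n <- length(r)
  # moment start: s2 = mean(r^2)/2  =>  D = (s2 - 2 sig^2) / (2 dt), floored
  D_mom <- max(0, (mean(r^2) / 2 - 2 * sig^2) / (2 * dt))
  D_max <- max(1, 10 * D_mom, R_cap^2 / (4 * dt))

  if (!background) {
    if (all(r == 0)) {
      # degenerate: likelihood maximized at the smallest admissible scale
      return(structure(list(D_hat = 0, phi = 0, n_used = n,
                            log_likelihood = -.smdm_nll(0, 0, r, dt, sig, R_cap),
                            converged = TRUE), class = "smdm_fit"))
    }
    opt <- optimize(function(D) .smdm_nll(D, 0, r, dt, sig, R_cap),
                    interval = c(0, D_max), tol = tol)
    D_hat <- opt$minimum
    # Newton polish on the score; the no-background likelihood is unimodal in
    # s2 with root s2 = mean(r^2)/2, so a couple of steps reach ~1e-12.
    m2 <- mean(r^2)
    for (i in 1:4) {
      s2 <- 2 * D_hat * dt + 2 * sig^2
      score <- n * (2 * dt) * (m2 / (2 * s2^2) - 1 / s2)
      hess  <- n * (2 * dt)^2 * (1 / s2^2 - m2 / s2^3)
      if (!is.finite(score) || !is.finite(hess) || hess == 0) break
      step <- score / hess
      D_new <- D_hat - step
      if (!is.finite(D_new) || D_new < 0) break
      D_hat <- D_new
      if (abs(step) < tol * 1e-2) break
    }
    D_hat <- max(0, D_hat)
    ll <- -.smdm_nll(D_hat, 0, r, dt, sig, R_cap)
    return(structure(list(D_hat = D_hat, phi = 0, n_used = n,
                          log_likelihood = ll, converged = TRUE),
                     class = "smdm_fit"))
  }

  # joint (D, phi) fit: multi-start bounded quasi-Newton from the moment
  # estimate; the likelihood is well-behaved but phi can sit on a boundary
  starts <- expand.grid(D = unique(c(D_mom, D_mom / 2, 2 * D_mom + 0.1)),
                        phi = c(0.01, 0.1, 0.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(max(starts$D[i], 1e-6), starts$phi[i]),
            function(p) .smdm_nll(p[1], p[2], r, dt, sig, R_cap),
            method = "L-BFGS-B",
            lower = c(0, 0), upper = c(D_max, 1),
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(D_hat = D_mom, phi = 0, n_used = n,
                          log_likelihood = -.smdm_nll(D_mom, 0, r, dt, sig, R_cap),
                          converged = FALSE), class = "smdm_fit"))
  }
  structure(list(D_hat = max(0, best$par[1]), phi = best$par[2], n_used = n,
                 log_likelihood = -best$value,
                 converged = best$convergence == 0),
            class = "smdm_fit")
}

#' @export
print.smdm_fit <- function(x, ...) {
  if (!x$converged && is.na(x$D_hat)) {
    cat(sprintf("<smdm_fit> masked (n = %d below threshold)\n", x$n_used))
  } else {
    cat(sprintf("<smdm_fit> D = %.4g um^2/s, phi = %.3g, n = %d, logL = %.4g\n",
                x$D_hat, x$phi, x$n_used, x$log_likelihood))
  }
  invisible(x)
}

#' Map local diffusivity by per-bin maximum likelihood
#'
#' Bins the displacement table on the lattice and applies
#' [fit_diffusivity()] to each bin's displacement magnitudes; bins holding
#' fewer than `n_min` displacements are masked.
#'
#' @inheritParams bin_displacements
#' @inheritParams fit_diffusivity
#' @param table displacement data.frame (`x0_um, y0_um, dx_um, dy_um`).
#' @return object of class `diffusivity_map`: matrices `D_hat`, `n`,
#'   `phi`, logical `masked`, the `lattice`, and `median_D` over unmasked
#'   bins.
#' @export
map_diffusivity <- function(table, lattice, settings, background = FALSE,
                            n_min = 10L, tol = 1e-8) {
  stopifnot(inherits(lattice, "bin_lattice"))
  nr <- lattice$n_rows; nc <- lattice$n_cols
  D_hat <- matrix(NA_real_, nr, nc)
  phi <- matrix(NA_real_, nr, nc)
  counts <- matrix(0L, nr, nc)
  if (nrow(table) == 0L) {
    warning("empty displacement table: fully masked map", call. = FALSE)
    return(structure(list(D_hat = D_hat, phi = phi, n = counts,
                          masked = matrix(TRUE, nr, nc), lattice = lattice,
                          median_D = NA_real_, n_out_of_field = 0L),
                     class = "diffusivity_map"))
  }
  b <- bin_displacements(table, lattice)
  r_all <- sqrt(table$dx_um^2 + table$dy_um^2)
  ok <- !is.na(b$bin_id)
  by_bin <- split(r_all[ok], b$bin_id[ok])
  for (id_chr in names(by_bin)) {
    id <- as.integer(id_chr)
    row <- ((id - 1L) %% nr) + 1L
    col <- ((id - 1L) %/% nr) + 1L
    rs <- by_bin[[id_chr]]
    counts[row, col] <- length(rs)
    fit <- fit_diffusivity(rs, settings, background = background,
                           n_min = n_min, tol = tol)
    if (fit$converged) {
      D_hat[row, col] <- fit$D_hat
      phi[row, col] <- fit$phi
    }
  }
  masked <- is.na(D_hat)
  if (all(masked))
    warning("all bins below the minimum-count threshold", call. = FALSE)
  structure(list(D_hat = D_hat, phi = phi, n = counts, masked = masked,
                 lattice = lattice,
                 median_D = if (all(masked)) NA_real_ else median(D_hat[!masked]),
                 n_out_of_field = b$n_out_of_field),
            class = "diffusivity_map")
}

#' @export
print.diffusivity_map <- function(x, ...) {
  cat(sprintf("<diffusivity_map> %d x %d bins (%.3g um), %d unmasked, median D = %.3g um^2/s\n",
              x$lattice$n_rows, x$lattice$n_cols, x$lattice$bin_size,
              sum(!x$masked), x$median_D))
  invisible(x)
}

#' Displacement histogram with the fitted model curve
#'
#' Density-normalized histogram of displacement magnitudes plus the fitted
#' model PDF sampled on a regular grid over `[0, R_cap]` — the standard
#' per-region diagnostic of an SMdM fit.
#'
#' @param r displacement magnitudes, um.
#' @param fit an `smdm_fit`.
#' @param settings the [acquisition_settings()] used for the fit.
#' @param n_bins number of histogram bins (>= 2).
#' @param n_curve number of curve samples.
#' @return list of class `smdm_histogram`: `histogram` (data.frame
#'   `r_mid, density, count`), `curve` (data.frame `r, pdf`), `breaks`.
#' @export
displacement_histogram <- function(r, fit, settings, n_bins = 40L,
                                   n_curve = 256L) {
  if (length(r) == 0L) stop_input("no displacement magnitudes supplied")
  if (n_bins < 2L) stop_input("`n_bins` must be >= 2")
  R_cap <- settings$capture_radius
  breaks <- seq(0, R_cap, length.out = n_bins + 1L)
  h <- hist(pmin(r, R_cap), breaks = breaks, plot = FALSE)
  rg <- seq(0, R_cap, length.out = n_curve)
  s2 <- 2 * fit$D_hat * settings$dt + 2 * settings$sigma_loc^2
  pdf_sig <- if (s2 > 0) (rg / s2) * exp(-rg^2 / (2 * s2)) else as.numeric(rg == 0)
  phi <- if (is.na(fit$phi)) 0 else fit$phi
  pdf <- (1 - phi) * pdf_sig + phi * 2 * rg / R_cap^2
  structure(list(histogram = data.frame(r_mid = h$mids, density = h$density,
                                        count = h$counts),
                 curve = data.frame(r = rg, pdf = pdf),
                 breaks = breaks, fit = fit, settings = settings),
            class = "smdm_histogram")
}

#' Plot an SMdM displacement histogram with its fit
#'
#' Draws on the current graphics device; the fitted D is annotated as in
#' the conventional per-region SMdM diagnostic panel.
#'
#' @param x an `smdm_histogram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.smdm_histogram <- function(x, ...) {
  plot(x$histogram$r_mid, x$histogram$density, type = "h", lwd = 6,
       col = "grey70", lend = 1, xlab = "displacement (um)",
       ylab = "probability density", ...)
  lines(x$curve$r, x$curve$pdf, col = "blue", lwd = 2)
  legend("topright", bty = "n",
         legend = sprintf("D = %.2f um²/s", x$fit$D_hat))
  invisible(x)
}

#' Render a diffusivity map as a color-coded image
#'
#' @param x a `diffusivity_map`.
#' @param D_range display range, um^2/s; a fixed `[0, 10]` window keeps
#'   filament and dispersed states on one comparable scale.
#' @param ... passed to [graphics::image()].
#' @export
plot.diffusivity_map <- function(x, D_range = c(0, 10), ...) {
  z <- pmin(pmax(x$D_hat, D_range[1]), D_range[2])
  z[x$masked] <- NA
  # transpose + flip so row 1 renders at the top (y downward convention)
  image(t(z)[, rev(seq_len(nrow(z))), drop = FALSE], zlim = D_range,
        col = hcl.colors(64, "Spectral", rev = TRUE), axes = FALSE,
        xlab = "", ylab = "", ...)
  box()
  mtext(sprintf("median D = %.2f um²/s", x$median_D), side = 3, line = 0.2,
        cex = 0.8)
  invisible(x)
}
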