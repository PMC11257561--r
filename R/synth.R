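# Synthetic single-molecule displacement generator.
#
# Emulates the statistical structure of an SMdM acquisition: molecules drawn
# from a two-population spatial diffusivity field (filament-bound, slow; and
# dispersed oligomers, fast) take one 2D Brownian step over the paired-frame
# interval dt, observed with Gaussian localization error in both frames.

#' Acquisition settings for a paired-frame SMdM experiment
#'
#' @param dt pair interval in seconds. The transient displacements are
#'   accumulated between paired stroboscopic excitation pulses across tandem
#'   camera frames; 1 ms is the conventional window.
#' @param sigma_loc per-axis localization precision in micrometres. The error
#'   contributes to both paired localizations, so each displacement axis gains
#'   variance `2 * sigma_loc^2` on top of the Brownian `2 * D * dt`.
#' @param field_width,field_height extent of the simulated field of view, um.
#' @param capture_radius maximum recordable displacement magnitude, um;
#'   displacements beyond it are discarded (and counted), mirroring the
#'   finite matching radius of displacement pairing.
#' @param seed integer seed; identical seed and settings give bit-identical
#'   output tables.
#' @return an object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(dt = 1e-3, sigma_loc = 0.02,
                                 field_width = 12.8, field_height = 12.8,
                                 capture_radius = 0.8, seed = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_input("`dt` must be a single positive number (seconds)")
  if (!is.numeric(sigma_loc) || sigma_loc < 0)
    stop_input("`sigma_loc` must be >= 0")
  if (capture_radius <= 0) stop_input("`capture_radius` must be > 0")
  if (field_width <= 0 || field_height <= 0)
    stop_input("field dimensions must be positive")
  structure(list(dt = dt, sigma_loc = sigma_loc,
                 field_width = field_width, field_height = field_height,
                 capture_radius = capture_radius, seed = as.integer(seed)),
            class = "acquisition_settings")
}

#' Ground-truth diffusivity field with rasterized filaments
#'
#' Builds a gridded diffusivity field in which `n_filaments` random-walk
#' polylines are rasterized onto a boolean mask; bins on the mask carry
#' `D_bound` (the slow, filament-associated state) and bins off it `D_free`
#' (the fast, dispersed-oligomer state). The geometry is a synthetic stand-in
#' for a cell's filament network, not a mechanical model.
#'
#' @param grid_shape integer `c(n_rows, n_cols)`.
#' @param n_filaments number of filament polylines (0 gives a uniform field).
#' @param D_bound,D_free diffusion coefficients, um^2/s. Defaults follow the
#'   two regimes seen for filament-bound versus dispersed vimentin fusions
#'   (about 1.5 and 7 um^2/s).
#' @param bound_fraction fraction of simulated molecules assigned to the
#'   filament population, in `[0, 1]`.
#' @param seed integer seed for the filament geometry.
#' @param bin_size lattice bin edge, um.
#' @return an object of class `diffusivity_field`: matrices `D` and `mask`
#'   (row-major display convention: row 1 at the top, y increasing downward),
#'   plus the lattice descriptor.
#' @export
make_filament_field <- function(grid_shape = c(32L, 32L), n_filaments = 10L,
                                D_bound = 1.5, D_free = 7, bound_fraction = 0.5,
                                seed = 1L, bin_size = 0.4) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape <= 0L))
    stop_input("`grid_shape` must be two positive integers (rows, cols)")
  if (n_filaments < 0) stop_input("`n_filaments` must be >= 0")
  if (D_bound < 0 || D_free < 0) stop_input("diffusivities must be >= 0")
  if (bound_fraction < 0 || bound_fraction > 1)
    stop_input("`bound_fraction` must lie in [0, 1]")
  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  mask <- matrix(FALSE, nr, nc)
  if (n_filaments > 0) {
    mask <- local_seed(seed, {
      m <- mask
      n_steps <- 3L * max(nr, nc)
      for (f in seq_len(n_filaments)) {
        r <- runif(1, 1, nr); c <- runif(1, 1, nc)
        theta <- runif(1, 0, 2 * pi)
        for (s in seq_len(n_steps)) {
          ri <- as.integer(round(r)); ci <- as.integer(round(c))
          if (ri < 1L || ri > nr || ci < 1L || ci > nc) break
          m[ri, ci] <- TRUE
          # weakly persistent walk: filaments are locally straight
          theta <- theta + rnorm(1, 0, 0.25)
          r <- r + sin(theta); c <- c + cos(theta)
        }
      }
      m
    })
  }
  D <- matrix(D_free, nr, nc)
  D[mask] <- D_bound
  structure(list(D = D, mask = mask, bound_fraction = bound_fraction,
                 bin_size = bin_size, origin = c(0, 0),
                 D_bound = D_bound, D_free = D_free),
            class = "diffusivity_field")
}

#' @export
print.diffusivity_field <- function(x, ...) {
  cat(sprintf("<diffusivity_field> %d x %d bins of %.3g um, %.1f%% masked, D in [%.3g, %.3g] um^2/s\n",
              nrow(x$D), ncol(x$D), x$bin_size, 100 * mean(x$mask),
              min(x$D), max(x$D)))
  invisible(x)
}

# bin (row, col) -> uniform position within that bin, in um (y downward)
.bin_to_xy <- function(row, col, bin_size, origin) {
  list(x = origin[1] + (col - 1 + runif(length(col))) * bin_size,
       y = origin[2] + (row - 1 + runif(length(row))) * bin_size)
}

# position (x, y) in um -> (row, col) indices, clamped to the grid
.xy_to_bin <- function(x, y, field) {
  col <- pmin(ncol(field$D), pmax(1L, 1L + floor((x - field$origin[1]) / field$bin_size)))
  row <- pmin(nrow(field$D), pmax(1L, 1L + floor((y - field$origin[2]) / field$bin_size)))
  cbind(as.integer(row), as.integer(col))
}

#' Simulate paired-frame single-molecule displacements
#'
#' Places `n_molecules` at random origins — bound molecules uniformly within
#' filament-mask bins, free molecules uniformly over the field, split by the
#' field's `bound_fraction` — and draws each displacement component as a
#' zero-mean Gaussian with variance `2 * D_local * dt + 2 * sigma_loc^2`,
#' where `D_local` is the field value at the origin bin. Displacements whose
#' magnitude exceeds the capture radius are discarded and counted, so
#' `nrow(records) + n_discarded == n_molecules` exactly.
#'
#' @param field a [make_filament_field()] object.
#' @param settings an [acquisition_settings()] object.
#' @param n_molecules number of molecules to simulate.
#' @param seed optional seed overriding `settings$seed`.
#' @return a list of class `displacement_set`: `records` (data.frame with
#'   columns `x0_um, y0_um, dx_um, dy_um, label`), `n_discarded`, `settings`.
#' @export
simulate_displacements <- function(field, settings, n_molecules, seed = NULL) {
  stopifnot(inherits(field, "diffusivity_field"),
            inherits(settings, "acquisition_settings"))
  if (n_molecules <= 0) stop_input("`n_molecules` must be > 0")
  n_molecules <- as.integer(n_molecules)
  if (field$bound_fraction > 0 && !any(field$mask))
    stop_input("bound_fraction > 0 but the filament mask is empty")
  seed <- seed %||% settings$seed
  local_seed(seed, {
    n_bound <- rbinom(1L, n_molecules, field$bound_fraction)
    n_free <- n_molecules - n_bound
    mask_idx <- which(field$mask, arr.ind = TRUE)

    xs <- numeric(0); ys <- numeric(0); lab <- character(0)
    if (n_bound > 0) {
      pick <- mask_idx[sample.int(nrow(mask_idx), n_bound, replace = TRUE), , drop = FALSE]
      p <- .bin_to_xy(pick[, 1], pick[, 2], field$bin_size, field$origin)
      xs <- c(xs, p$x); ys <- c(ys, p$y)
      lab <- c(lab, rep("bound", n_bound))
    }
    if (n_free > 0) {
      xs <- c(xs, field$origin[1] + runif(n_free) * ncol(field$D) * field$bin_size)
      ys <- c(ys, field$origin[2] + runif(n_free) * nrow(field$D) * field$bin_size)
      lab <- c(lab, rep("free", n_free))
    }
    bins <- .xy_to_bin(xs, ys, field)
    D_local <- field$D[bins]
    # per-axis variance: Brownian 2 D dt plus localization error in both frames
    s <- sqrt(2 * D_local * settings$dt + 2 * settings$sigma_loc^2)
    dx <- rnorm(n_molecules, 0, s)
    dy <- rnorm(n_molecules, 0, s)
    keep <- sqrt(dx^2 + dy^2) <= settings$capture_radius

    records <- data.frame(x0_um = xs[keep], y0_um = ys[keep],
                          dx_um = dx[keep], dy_um = dy[keep],
                          label = lab[keep], stringsAsFactors = FALSE)
    structure(list(records = records,
                   n_discarded = sum(!keep),
                   n_requested = n_molecules,
                   settings = settings, seed = seed),
              class = "displacement_set")
  })
}

#' @export
print.displacement_set <- function(x, ...) {
  cat(sprintf("<displacement_set> %d records (%d discarded beyond R_cap = %.3g um), dt = %g s\n",
              nrow(x$records), x$n_discarded, x$settings$capture_radius,
              x$settings$dt))
  invisible(x)
}

#' Simulate a disassembly/reassembly timecourse
#'
#' Interpolates `bound_fraction` linearly between two congruent endpoint
#' fields and simulates an independent displacement table per step; step
#' seeds are derived deterministically from `settings$seed`, so the whole
#' timecourse is reproducible from one master seed.
#'
#' @param field_start,field_end congruent [make_filament_field()] objects.
#' @param n_steps number of steps (>= 2); step 1 is `field_start`'s
#'   condition and step `n_steps` is `field_end`'s.
#' @param settings an [acquisition_settings()] object.
#' @param n_molecules_per_step molecules per step.
#' @return list of class `displacement_timecourse`: `steps` (list of
#'   `displacement_set`), `bound_fractions`, `fields`.
#' @export
simulate_timecourse <- function(field_start, field_end, n_steps, settings,
                                n_molecules_per_step) {
  stopifnot(inherits(field_start, "diffusivity_field"),
            inherits(field_end, "diffusivity_field"))
  if (!identical(dim(field_start$D), dim(field_end$D)))
    stop_input("endpoint fields must have congruent grids")
  if (n_steps < 2) stop_input("`n_steps` must be >= 2")
  fr <- seq(field_start$bound_fraction, field_end$bound_fraction,
            length.out = n_steps)
  steps <- vector("list", n_steps)
  fields <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    fk <- field_start
    fk$bound_fraction <- fr[k]
    fields[[k]] <- fk
    steps[[k]] <- simulate_displacements(fk, settings, n_molecules_per_step,
                                         seed = derive_seed(settings$seed, k))
  }
  structure(list(steps = steps, bound_fractions = fr, fields = fields),
            class = "displacement_timecourse")
}

#' Write a displacement table to CSV with a JSON metadata sidecar
#'
#' The CSV carries the header `x0_um,y0_um,dx_um,dy_um,label`; the sidecar
#' (`<path>.json`) records acquisition settings, seed and discard count, so
#' a dataset is self-describing and byte-reproducible.
#'
#' @param x a `displacement_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_displacements <- function(x, path) {
  stopifnot(inherits(x, "displacement_set"))
  write.csv(x$records, path, row.names = FALSE, quote = FALSE)
  meta <- list(schema = "smdmtools/displacements/v1",
               settings = unclass(x$settings), seed = x$seed,
               n_records = nrow(x$records), n_discarded = x$n_discarded)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
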