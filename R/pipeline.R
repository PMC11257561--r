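# Pipeline plumbing: validated table I/O, a reproducible end-to-end demo of
# the full inference chain on synthetic data, and versioned JSON reports.

.displacement_cols <- c("x0_um", "y0_um", "dx_um", "dy_um")

#' Read and validate a displacement table
#'
#' Expects the `x0_um,y0_um,dx_um,dy_um[,label]` CSV schema written by
#' [write_displacements()]. Malformed rows (non-numeric coordinate fields)
#' are rejected individually with their line numbers reported in a warning;
#' missing columns are a hard error.
#'
#' @param path CSV path.
#' @return data.frame of valid rows, with attribute `n_rejected`.
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.displacement_cols, names(tab))
  if (length(missing))
    stop_input("displacement table ", path, " lacks column(s): ",
               paste(missing, collapse = ", "))
  num <- lapply(tab[.displacement_cols], function(x) suppressWarnings(as.numeric(x)))
  bad <- Reduce(`|`, lapply(num, function(x) !is.finite(x)))
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s", sum(bad),
                    paste(head(which(bad) + 1L, 10), collapse = ", ")),
            call. = FALSE)
  }
  out <- data.frame(num, stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  if ("label" %in% names(tab)) out$label <- tab$label[!bad]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Default configuration for the demo pipeline
#'
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @param n_molecules displacements per simulated state. The full-scale
#'   acquisition is ~1e5 per cell; reduce for quick runs.
#' @param grid_shape field grid `c(rows, cols)`.
#' @param n_filaments filaments in the synthetic geometry.
#' @param D_bound,D_free ground-truth diffusivities, um^2/s.
#' @param n_timecourse_steps steps in the disassembly and reassembly legs.
#' @param sequences named character vector of FASTA paths for charge
#'   analysis (defaults to the bundled vimentin and GFAP fixtures).
#' @param buffer_presets preset names for the ionics table.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_molecules = 1e5,
                            grid_shape = c(32L, 32L), n_filaments = 12L,
                            D_bound = 1.5, D_free = 7,
                            n_timecourse_steps = 3L,
                            sequences = c(
                              vimentin = system.file("extdata",
                                "vimentin_P08670_synthetic.fasta",
                                package = "smdmtools"),
                              gfap = system.file("extdata",
                                "gfap_P14136_synthetic.fasta",
                                package = "smdmtools")),
                            buffer_presets = c("water",
                              "phosphate5_pH7.3_glucose350", "dpbs",
                              "acetate5_pH5.0", "capso5_pH9.0",
                              "capso5_pH10.0"),
                            out_dir = tempfile("smdm_demo_")) {
  structure(list(seed = as.integer(seed), n_molecules = n_molecules,
                 grid_shape = as.integer(grid_shape),
                 n_filaments = as.integer(n_filaments),
                 D_bound = D_bound, D_free = D_free,
                 n_timecourse_steps = as.integer(n_timecourse_steps),
                 sequences = sequences, buffer_presets = buffer_presets,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end demo on synthetic data
#'
#' Reproduces the inference chain on synthetic inputs: simulate three
#' assembly states (filament, disassembled, reassembled), fit a diffusivity
#' map and displacement histogram per state, infer the average oligomer size
#' from the disassembled-state median D, compute charge curves and pI for
#' the configured sequences, and tabulate ionic strength / Debye length /
#' osmolarity for the configured buffer presets. All artifacts land under
#' `config$out_dir` and are indexed by a single JSON manifest.
#'
#' @param config a [pipeline_config()].
#' @param plots write PNG renderings (off by default so headless runs never
#'   depend on a graphics device).
#' @return the manifest list, invisibly; `$paths` names every artifact.
#' @export
run_demo <- function(config = pipeline_config(), plots = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  paths <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop_input("demo stage '", name, "' failed: ", conditionMessage(e),
                 "\nconfig: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE)))
  }

  settings <- acquisition_settings(seed = config$seed,
                                   field_width = config$grid_shape[2] * 0.4,
                                   field_height = config$grid_shape[1] * 0.4)
  field <- stage("field", make_filament_field(
    config$grid_shape, config$n_filaments, config$D_bound, config$D_free,
    bound_fraction = 0.85, seed = config$seed))
  lattice <- lattice_from_field(field)
  paths["field_tiff"] <- out("true_field.tif")
  write_field_tiff(field$D, paths[["field_tiff"]], bin_size_um = field$bin_size)

  # disassembled: the filaments are gone, so the field is uniformly fast
  states <- list(filament = 0.85, disassembled = 0.0, reassembled = 0.85)
  maps <- list(); state_summaries <- list()
  for (i in seq_along(states)) {
    nm <- names(states)[i]
    f <- field; f$bound_fraction <- states[[i]]
    if (nm == "disassembled") f$D[] <- config$D_free
    sim <- stage(paste0("simulate_", nm), simulate_displacements(
      f, settings, config$n_molecules, seed = derive_seed(config$seed, i)))
    paths[paste0("displacements_", nm)] <- out(sprintf("displacements_%s.csv", nm))
    write_displacements(sim, paths[[paste0("displacements_", nm)]])
    m <- stage(paste0("map_", nm),
               map_diffusivity(sim$records, lattice, settings))
    maps[[nm]] <- m
    paths[paste0("dmap_", nm)] <- out(sprintf("dmap_%s.tif", nm))
    write_field_tiff(m$D_hat, paths[[paste0("dmap_", nm)]],
                     bin_size_um = lattice$bin_size)
    r <- sqrt(sim$records$dx_um^2 + sim$records$dy_um^2)
    fit_all <- fit_diffusivity(r, settings)
    hs <- displacement_histogram(r, fit_all, settings)
    paths[paste0("hist_", nm)] <- out(sprintf("histogram_%s.csv", nm))
    write.csv(hs$histogram, paths[[paste0("hist_", nm)]], row.names = FALSE)
    if (plots) {
      paths[paste0("dmap_png_", nm)] <- out(sprintf("dmap_%s.png", nm))
      png(paths[[paste0("dmap_png_", nm)]], 480, 480)
      plot(m); dev.off()
    }
    state_summaries[[nm]] <- list(bound_fraction = states[[i]],
                                  median_D = m$median_D,
                                  pooled_D = fit_all$D_hat,
                                  n_records = nrow(sim$records),
                                  n_discarded = sim$n_discarded)
  }

  # oligomer inference from the disassembled state, with the conventional
  # 3:1 free-FP reference ratio
  D_disp <- maps$disassembled$median_D
  olig <- stage("oligomer", oligomer_size_from_D(
    D_measured = D_disp, D_reference = 3 * D_disp,
    mw_reference = 27, mw_construct = 81, mw_vimentin = 54))
  paths["oligomer"] <- out("oligomer_report.json")
  write_report(olig, paths[["oligomer"]])

  charge <- list()
  for (nm in names(config$sequences)) {
    seqs <- stage(paste0("fasta_", nm), read_fasta(config$sequences[[nm]]))
    cc <- charge_curve(seqs[[1]], pka = "protcalc")
    cc$name <- nm
    paths[paste0("charge_curve_", nm)] <- out(sprintf("charge_curve_%s.csv", nm))
    write.csv(cc$curve, paths[[paste0("charge_curve_", nm)]], row.names = FALSE)
    charge[[nm]] <- list(pI = cc$pI,
                         Z_pH7.3 = net_charge(seqs[[1]], 7.3, pka = "protcalc"),
                         mw_kDa = molecular_weight(seqs[[1]]))
  }

  buffers <- lapply(config$buffer_presets, function(p) {
    st <- speciate(p)
    list(preset = p, pH = st$pH, I_M = st$I_M,
         debye_nm = if (is.finite(st$debye_nm)) st$debye_nm else "Inf",
         osmolarity_mOsm = st$osmolarity_mOsm,
         repulsion_index = list(
           provenance = "interpretive",
           value = as.numeric(repulsion_index(-18, 5,
             if (is.finite(st$debye_nm)) st$debye_nm else 1e9))))
  })
  paths["buffers"] <- out("buffer_ionics.json")
  write_report(buffers, paths[["buffers"]])

  manifest <- list(schema = "smdmtools/demo-manifest/v1",
                   seed = config$seed, config = unclass(config),
                   states = state_summaries,
                   oligomer = list(n_vimentin = olig$n_vimentin,
                                   rounded10 = olig$n_vimentin_rounded10),
                   charge = charge, buffers = buffers,
                   paths = as.list(paths))
  paths["manifest"] <- out("manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$paths <- as.list(paths)
  invisible(manifest)
}

#' Write a versioned JSON report
#'
#' Strips classes and serializes with full numeric precision under a
#' `schema` header, so reports round-trip without loss.
#'
#' @param results any serializable structure (package result objects are
#'   unclassed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  payload <- list(schema = "smdmtools/report/v1",
                  generated_by = paste0("smdmtools ",
                    as.character(utils::packageVersion("smdmtools"))),
                  results = rapply(list(results), unclass, how = "replace")[[1]])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
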