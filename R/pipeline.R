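# Full-analysis orchestration: cluster -> shape -> contacts -> conformation
# -> surface, with a resolved-config run manifest. The output contract is
# CSV + JSON; plotting is left to downstream tools reading the CSVs.

#' Build a run configuration
#'
#' @param topology topology file path (PDB or GRO), or `NULL` when
#'   `trajectory` is an in-memory `"traj"`.
#' @param trajectory trajectory file path, or a `"traj"` object.
#' @param out_dir output directory (created if absent).
#' @param cutoff heavy-atom contact cutoff, nm.
#' @param window_ns trailing analysis window, ns.
#' @param drmsd_bin DRMSD histogram bin width, Angstrom.
#' @param rama_bin Ramachandran bin width, degrees.
#' @param hbond_d,hbond_angle hydrogen-bond criterion (nm, degrees).
#' @param contact_z,persistence surface-contact criterion (nm, fraction of
#'   window frames).
#' @param references named list of `"refdist"` objects or file paths;
#'   defaults to the shipped fibril-like and surface-like references.
#' @param size_weighting `"peptide"` or `"cluster"` (size histogram).
#' @param stride_ps frame spacing when loading a file without times.
#' @param gyration_frames number of trailing frames given per-oligomer
#'   gyration spectra (0 = all frames).
#' @return object of class `"run_config"`.
#' @export
run_config <- function(topology = NULL, trajectory = NULL, out_dir = "surfagg_out",
                       cutoff = 0.4, window_ns = 100, drmsd_bin = 0.1,
                       rama_bin = 5, hbond_d = 0.35, hbond_angle = 30,
                       contact_z = 0.5, persistence = 0.5,
                       references = NULL, size_weighting = "peptide",
                       stride_ps = 1, gyration_frames = 0L) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path config file path.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

.resolve_references <- function(refs) {
  if (is.null(refs))
    return(list(fibril = reference_fibril(), surface = reference_surface()))
  out <- lapply(seq_along(refs), function(k) {
    r <- refs[[k]]
    if (inherits(r, "refdist")) r
    else read_reference(r, label = names(refs)[k])
  })
  names(out) <- names(refs)
  out
}

#' Run the full analysis pipeline
#'
#' Produces, per run: `largest_oligomer.csv`, `size_histogram.csv`,
#' `gyration.csv`, `single_peptide_gyration.csv`, `contact_map.csv`,
#' `hbond_map.csv` (when the topology carries amide hydrogens),
#' `drmsd_hist_<ref>.csv`, `ramachandran.csv`,
#' `ramachandran_quadrants.csv`, and for surface systems `z_profile.csv`,
#' `com_z_series.csv` and `adsorption.csv`, plus a `manifest.json` with the
#' resolved configuration, input hashes and output hashes. Deterministic
#' given config and inputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of the in-memory results, of class
#'   `"analysis_report"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (inherits(config$trajectory, "traj")) {
    traj <- config$trajectory
    inputs <- list()
  } else {
    if (is.null(config$topology)) stop("config$topology is required")
    sysld <- load_system(config$topology)
    traj <- load_trajectory(sysld$system, config$trajectory,
                            stride_ps = config$stride_ps, box = sysld$box)
    inputs <- list(topology = unname(tools::md5sum(config$topology)),
                   trajectory = unname(tools::md5sum(config$trajectory)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  refs <- .resolve_references(config$references)
  report <- list(config = config)
  written <- character(0)
  emit <- function(df, file) {
    write.csv(df, outp(file), row.names = FALSE)
    written <<- c(written, file)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  run_stage("clustering", {
    los <- largest_oligomer_series(traj, config$cutoff)
    emit(los, "largest_oligomer.csv")
    report$largest_oligomer <- los
    sh <- tryCatch(size_histogram(traj, config$cutoff, config$window_ns,
                                  config$size_weighting),
                   error = function(e) size_histogram(
                     traj, config$cutoff,
                     (traj$times[n_frames(traj)] - traj$times[1]) / 1000,
                     config$size_weighting))
    emit(data.frame(size = as.integer(names(sh$p)), p = unname(sh$p)),
         "size_histogram.csv")
    report$size_histogram <- sh
  })

  run_stage("shape", {
    gf <- seq_len(n_frames(traj))
    if (config$gyration_frames > 0L)
      gf <- tail(gf, config$gyration_frames)
    gy <- oligomer_gyration_series(traj, config$cutoff, frames = gf)
    emit(gy, "gyration.csv")
    report$gyration <- gy
    sp <- single_peptide_spectrum(traj, config$window_ns)
    emit(sp, "single_peptide_gyration.csv")
    report$single_peptide_gyration <- sp
  })

  run_stage("contacts", {
    if (traj$system$n_peptides >= 2L) {
      cm <- residue_contact_map(traj, config$window_ns, config$cutoff)
      write_matrix_csv(cm$map, outp("contact_map.csv"))
      written <- c(written, "contact_map.csv")
      report$contact_map <- cm
      hb <- tryCatch(hydrogen_bond_map(traj, config$window_ns,
                                       config$hbond_d, config$hbond_angle),
                     error = function(e) NULL)
      if (!is.null(hb)) {
        write_matrix_csv(hb$map, outp("hbond_map.csv"))
        written <- c(written, "hbond_map.csv")
        report$hbond_map <- hb
      }
    }
  })

  run_stage("conformation", {
    has_bb <- all(c("N", "CA", "C") %in% traj$system$atoms$name)
    if (has_bb || any(traj$system$atoms$name == "CA")) {
      dh <- drmsd_histograms(traj, refs, config$window_ns, config$drmsd_bin)
      for (nm in names(dh)) {
        emit(dh[[nm]]$hist, paste0("drmsd_hist_", nm, ".csv"))
        emit(dh[[nm]]$series, paste0("drmsd_series_", nm, ".csv"))
      }
      report$drmsd <- dh
    }
    if (has_bb) {
      ra <- ramachandran(traj, config$window_ns, config$rama_bin)
      mids <- ra$breaks[-1] - config$rama_bin / 2
      long <- expand.grid(phi = mids, psi = mids)
      long$density <- as.vector(ra$density)
      emit(long, "ramachandran.csv")
      emit(data.frame(quadrant = names(ra$quadrants),
                      occupancy = unname(ra$quadrants)),
           "ramachandran_quadrants.csv")
      report$ramachandran <- ra
    }
  })

  if (!is.null(traj$system$surface)) run_stage("surface", {
    zp <- z_profile(traj, config$window_ns)
    rz <- data.frame(residue = rownames(zp$residue), zp$residue,
                     check.names = FALSE)
    write.csv(rz, outp("z_profile.csv"), row.names = FALSE)
    written <- c(written, "z_profile.csv")
    emit(zp$com_series, "com_z_series.csv")
    report$z_profile <- zp
    ad <- classify_adsorption(traj, config$window_ns, config$contact_z,
                              config$persistence)
    emit(data.frame(peptide = seq_along(ad$adsorbed),
                    adsorbed = ad$adsorbed,
                    contact_fraction = ad$contact_fraction,
                    label = ad$label),
         "adsorption.csv")
    report$adsorption <- ad
  })

  manifest <- list(
    package = "surfagg",
    version = as.character(utils::packageVersion("surfagg")),
    config = .serialisable_config(config),
    references = lapply(refs, function(r)
      list(label = r$label, n_residues = r$n_residues,
           distances_nm = r$r)),
    inputs = inputs,
    n_frames = n_frames(traj),
    window_ns = config$window_ns,
    outputs = as.list(vapply(sort(unique(written)), function(f)
      unname(tools::md5sum(outp(f))), character(1))))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$manifest <- manifest
  class(report) <- "analysis_report"
  invisible(report)
}

.serialisable_config <- function(config) {
  cfg <- unclass(config)
  cfg$trajectory <- if (inherits(cfg$trajectory, "traj")) "<in-memory>"
                    else cfg$trajectory
  cfg$references <- if (is.null(cfg$references)) "shipped defaults"
                    else names(cfg$references)
  cfg
}

#' Compare analysis runs side by side
#'
#' Summarises each run's DRMSD histograms (peak position and probability
#' mass below 1 Angstrom per reference), Ramachandran quadrant occupancies
#' and mean oligomer gyration spectra, reading only the CSV outputs of
#' [run_pipeline()].
#'
#' @param dirs character vector (length >= 2) of run output directories.
#' @return data.frame with one row per (run, quantity).
#' @export
compare_runs <- function(dirs) {
  stopifnot(length(dirs) >= 2L)
  rows <- list()
  bins <- list()
  for (d in dirs) {
    run <- basename(normalizePath(d))
    for (f in list.files(d, pattern = "^drmsd_hist_.*\\.csv$")) {
      ref <- sub("^drmsd_hist_(.*)\\.csv$", "\\1", f)
      h <- read.csv(file.path(d, f))
      bw <- diff(h$mid[1:2])
      bins[[ref]] <- c(bins[[ref]], bw)
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, quantity = paste0("drmsd_peak_", ref),
        value = h$mid[which.max(h$density)])
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, quantity = paste0("drmsd_mass_below_1A_", ref),
        value = sum(h$density[h$mid < 1]) * bw)
    }
    qf <- file.path(d, "ramachandran_quadrants.csv")
    if (file.exists(qf)) {
      q <- read.csv(qf)
      for (r in seq_len(nrow(q)))
        rows[[length(rows) + 1L]] <- data.frame(
          run = run, quantity = paste0("quadrant_", q$quadrant[r]),
          value = q$occupancy[r])
    }
    gf <- file.path(d, "gyration.csv")
    if (file.exists(gf)) {
      g <- read.csv(gf)
      g <- g[g$size == max(g$size), ]   # largest oligomer
      for (nm in c("gmax", "gmid", "gmin"))
        rows[[length(rows) + 1L]] <- data.frame(
          run = run, quantity = paste0("mean_", nm, "_largest_oligomer"),
          value = mean(g[[nm]]))
    }
  }
  for (ref in names(bins))
    if (length(unique(round(bins[[ref]], 9))) > 1L)
      stop("runs use different DRMSD bin widths for reference '", ref,
           "'; rebin before comparing")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
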