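# CSV readers/writers for every supported data kind, JSON fit reports,
# and the pipeline orchestrator.

#' Read a typed data table from CSV
#'
#' One flat schema per data kind; the header row is mandatory and the
#' returned object is validated against its container invariants, so a
#' malformed file fails at load with a pointed message.
#'
#' Schemas (columns):
#' * `"titration"`: `added_volume_ul, lipid_stock_mM, intensity`; rows
#'   are cumulative additions, a leading row with `added_volume_ul = 0`
#'   is the initial reading.  Requires `protein_nM` and `volume_ul`.
#' * `"quenching"`: `quencher_molpct, response` (plus optional
#'   `response_kind` column, constant); mol% is converted to mole
#'   fraction unless `fraction = TRUE` says the column is already
#'   fractional.
#' * `"depth"`: `quencher_label`, and `F0_over_F` or `qp`, optional
#'   `include` (0/1); label depths resolved through `catalog`.
#' * `"decay"`: `time_ns, counts`; a matching IRF file (same schema)
#'   is given as `irf_path`.
#' * `"kinetics"`: `time_s, intensity`.
#' * `"spectrum"`: `wavelength_nm, intensity` and optional `blank`.
#'
#' @param path CSV file path.
#' @param kind one of `"titration"`, `"quenching"`, `"depth"`,
#'   `"decay"`, `"kinetics"`, `"spectrum"`.
#' @param protein_nM,volume_ul initial protein concentration (nM) and
#'   sample volume (uL) for titration files.
#' @param fraction for quenching files: set `TRUE` when the quencher
#'   column already holds mole fractions rather than mol%.
#' @param catalog label-depth catalog for depth files (default
#'   [quencher_depths()]).
#' @param irf_path IRF CSV for decay files.
#' @return the validated container of the matching type.
#' @export
read_table <- function(path, kind = c("titration", "quenching", "depth",
                                      "decay", "kinetics", "spectrum"),
                       protein_nM = NULL, volume_ul = NULL,
                       fraction = FALSE, catalog = quencher_depths(),
                       irf_path = NULL) {
  kind <- match.arg(kind)
  mq_check(file.exists(path), "invalid_argument",
           sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE)
  need <- function(cols) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      mq_stop("schema", sprintf("%s: missing column(s) %s", path,
                                paste(missing, collapse = ", ")))
    }
  }
  switch(kind,
    titration = {
      need(c("added_volume_ul", "lipid_stock_mM", "intensity"))
      mq_check(!is.null(protein_nM) && !is.null(volume_ul),
               "invalid_argument",
               "titration files need protein_nM and volume_ul")
      av <- df$added_volume_ul
      pos <- av > 0
      mq_check(all(diff(pos) >= 0), "validation",
               "zero-addition rows must precede all additions")
      conc <- correct_dilution(
        protein_nM * 1e-9, volume_ul,
        data.frame(added_volume = av[pos],
                   lipid_stock = df$lipid_stock_mM[pos] * 1e-3)
      )
      # one concentration row per CSV row: leading zero-addition rows
      # all sit at the initial concentrations
      idx <- cumsum(pos) + 1
      titration_curve(conc$protein_total[idx], conc$lipid_total[idx],
                      df$intensity, meta = list(path = path))
    },
    quenching = {
      need(c("quencher_molpct", "response"))
      q <- df$quencher_molpct
      if (!fraction) q <- q / 100
      rk <- if ("response_kind" %in% names(df)) {
        unique(df$response_kind)
      } else "intensity"
      mq_check(length(rk) == 1, "validation",
               "response_kind must be constant within a file")
      bad <- which(diff(q) <= 0)
      if (length(bad)) {
        mq_stop("validation",
                sprintf("%s: quencher column not strictly increasing at row %d",
                        path, bad[1] + 1))
      }
      quenching_series(q, df$response, response_kind = rk,
                       meta = list(path = path))
    },
    depth = {
      need("quencher_label")
      unknown <- setdiff(df$quencher_label, names(catalog))
      mq_check(!length(unknown), "validation",
               sprintf("%s: unknown quencher label(s) %s", path,
                       paste(unknown, collapse = ", ")))
      qp <- if ("qp" %in% names(df)) {
        df$qp
      } else if ("F0_over_F" %in% names(df)) {
        df$F0_over_F - 1
      } else {
        mq_stop("schema", sprintf("%s: need column qp or F0_over_F", path))
      }
      include <- if ("include" %in% names(df)) df$include != 0 else NULL
      depth_profile(unname(catalog[df$quencher_label]), qp,
                    include = include,
                    meta = list(path = path,
                                labels = df$quencher_label))
    },
    decay = {
      need(c("time_ns", "counts"))
      mq_check(!is.null(irf_path), "invalid_argument",
               "decay files need a matching irf_path")
      mq_check(file.exists(irf_path), "invalid_argument",
               sprintf("file not found: %s", irf_path))
      irf <- read.csv(irf_path, check.names = FALSE)
      mq_check(all(c("time_ns", "counts") %in% names(irf)), "schema",
               "IRF file needs columns time_ns, counts")
      mq_check(nrow(irf) == nrow(df) &&
                 all(abs(irf$time_ns - df$time_ns) < 1e-9), "validation",
               "IRF and decay must share the channel grid")
      decay_trace(df$time_ns, df$counts, irf$counts,
                  meta = list(path = path, irf_path = irf_path))
    },
    kinetics = {
      need(c("time_s", "intensity"))
      kinetic_trace(df$time_s, df$intensity, meta = list(path = path))
    },
    spectrum = {
      need(c("wavelength_nm", "intensity"))
      emission_spectrum(df$wavelength_nm, df$intensity,
                        blank = if ("blank" %in% names(df)) df$blank,
                        meta = list(path = path))
    }
  )
}

#' Write a typed data table to CSV
#'
#' Inverse of [read_table()]: writes the container in the flat schema
#' its reader expects.
#'
#' @param x a data container (titration curves are written as the
#'   generic point table `protein_total, lipid_total, intensity`,
#'   which [titration_curve()] accepts directly).
#' @param path output CSV path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, ...) {
  df <- if (inherits(x, "quenching_series")) {
    data.frame(quencher_molpct = x$quencher_fraction * 100,
               response = x$response,
               response_kind = attr(x, "response_kind"))
  } else if (inherits(x, "depth_profile")) {
    labels <- attr(x, "meta")$labels
    if (is.null(labels)) {
      cat_depths <- quencher_depths()
      labels <- names(cat_depths)[match(x$quencher_depth, cat_depths)]
    }
    data.frame(quencher_label = labels, qp = x$qp,
               include = as.integer(x$include))
  } else if (inherits(x, "kinetic_trace")) {
    data.frame(time_s = x$time, intensity = x$intensity)
  } else if (inherits(x, "emission_spectrum")) {
    out <- data.frame(wavelength_nm = x$wavelength,
                      intensity = x$intensity)
    if (!is.null(x$blank)) out$blank <- x$blank
    out
  } else if (inherits(x, "decay_trace")) {
    data.frame(time_ns = x$channel_time, counts = x$counts,
               irf_counts = x$irf_counts)
  } else {
    as.data.frame(x)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

fit_to_record <- function(fit) {
  list(parameters = as.list(fit$coefficients),
       se = as.list(fit$se),
       rmsd = fit$gof$rmsd,
       chi2_red = fit$gof$chi2_red,
       n_points = fit$gof$n,
       flags = as.list(fit$flags))
}

#' Write a JSON fit report and a tidy per-point CSV
#'
#' @param fit any `quench_fit` object.
#' @param json_path output path for the JSON report (parameters,
#'   standard errors, rmsd, chi2_red, flags); `NULL` to skip.
#' @param csv_path output path for a tidy CSV of observed, fitted and
#'   residual values per point; `NULL` to skip.
#' @return the report list, invisibly.
#' @export
write_fit_report <- function(fit, json_path = NULL, csv_path = NULL) {
  rec <- fit_to_record(fit)
  if (!is.null(json_path)) {
    jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    obs <- fitted(fit) + residuals(fit)
    write.csv(data.frame(observed = obs, fitted = fitted(fit),
                         residual = residuals(fit)),
              csv_path, row.names = FALSE)
  }
  invisible(rec)
}

#' Run the full analysis pipeline over a set of input files
#'
#' Executes whichever stages have inputs listed in `config`, in the
#' order binding -> exposure -> depth -> decay -> kinetics -> spectrum,
#' skipping absent stages with a logged notice.  A stage whose fit
#' fails is recorded in the report (with the error message) and the
#' pipeline continues.
#'
#' @param config a named list, or the path of a JSON/YAML file holding
#'   one.  Recognised entries: `titration` (list: `path`, `protein_nM`,
#'   `volume_ul`), `quenching` (list or path), `depth` (list or path),
#'   `decay` (list: `path`, `irf_path`, optional `n_components`),
#'   `kinetics` (path), `spectrum` (path), `seed` (recorded in
#'   provenance), `meta` (free-form, recorded).
#' @param verbose print stage notices to stderr.
#' @return an object of class `"analysis_report"`: list with `results`
#'   (one record per executed stage), `skipped`, `errors`, and
#'   `provenance` (input hashes, seed, package version, timestamp).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  note <- function(...) if (verbose) message(sprintf(...))
  as_spec <- function(x) if (is.character(x)) list(path = x) else x

  results <- list(); errors <- list(); skipped <- character()
  files <- character()
  run_stage <- function(name, fun) {
    spec <- config[[name]]
    if (is.null(spec)) {
      skipped <<- c(skipped, name)
      note("stage '%s': no input, skipped", name)
      return(invisible(NULL))
    }
    spec <- as_spec(spec)
    files <<- c(files, unlist(spec[grepl("path", names(spec))]))
    out <- tryCatch(fun(spec), error = function(e) e)
    if (inherits(out, "error")) {
      errors[[name]] <<- conditionMessage(out)
      note("stage '%s': FAILED (%s)", name, conditionMessage(out))
    } else {
      results[[name]] <<- fit_to_record(out)
      note("stage '%s': ok", name)
    }
  }

  run_stage("titration", function(s) {
    fit_binding(read_table(s$path, "titration", protein_nM = s$protein_nM,
                           volume_ul = s$volume_ul))
  })
  run_stage("quenching", function(s) {
    fit_exposure(read_table(s$path, "quenching",
                            fraction = isTRUE(s$fraction)))
  })
  run_stage("depth", function(s) {
    fit_depth(read_table(s$path, "depth"))
  })
  run_stage("decay", function(s) {
    fit_decay(read_table(s$path, "decay", irf_path = s$irf_path),
              n_components = s$n_components %||% 3)
  })
  run_stage("kinetics", function(s) {
    fit_kinetics(read_table(s$path, "kinetics"))
  })
  run_stage("spectrum", function(s) {
    sp <- read_table(s$path, "spectrum")
    if (!is.null(sp$blank)) sp <- correct_scattering(sp)
    shape <- spectral_shape(sp)
    # adapt the shape metrics to the common record layout
    structure(list(coefficients = c(lambda_max = shape$lambda_max,
                                    fwhm = shape$fwhm),
                   se = c(lambda_max = NA_real_, fwhm = NA_real_),
                   gof = list(rmsd = NA_real_, chi2_red = NA_real_,
                              n = nrow(sp)),
                   flags = shape$flags),
              class = c("spectral_fit", "quench_fit"))
  })

  files <- files[file.exists(files)]
  report <- structure(
    list(results = results,
         skipped = as.list(skipped),
         errors = errors,
         provenance = list(
           inputs = as.list(tools::md5sum(unique(files))),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("memquench")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         meta = config$meta),
    class = "analysis_report")
  report
}

read_pipeline_config <- function(path) {
  mq_check(file.exists(path), "invalid_argument",
           sprintf("config not found: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    mq_check(requireNamespace("yaml", quietly = TRUE), "invalid_argument",
             "YAML configs require the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  for (nm in names(x$results)) {
    pars <- unlist(x$results[[nm]]$parameters)
    cat(sprintf("  %-10s %s\n", nm,
                paste(sprintf("%s=%.4g", names(pars), pars),
                      collapse = ", ")))
  }
  if (length(x$skipped)) {
    cat("  skipped:", paste(unlist(x$skipped), collapse = ", "), "\n")
  }
  for (nm in names(x$errors)) {
    cat(sprintf("  error in %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

#' Serialize / restore an analysis report
#'
#' The JSON round trip is lossless for every numeric and character
#' field (numbers are written at full precision).
#'
#' @param report an `analysis_report`.
#' @param path JSON file path.
#' @return `report_to_json` returns `path` invisibly;
#'   `report_from_json` the restored `analysis_report`.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "analysis_report")
}
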