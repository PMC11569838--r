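## Run configuration: a flat key = value text file (or an equivalent named
## list). Recognized keys are listed in `pipeline_keys`; anything else is
## rejected outright so typos fail fast instead of silently skipping stages.
pipeline_keys <- c("melting_file", "melting_Ct_uM", "series_file",
                   "mobility_file", "mobility_reference",
                   "spectra_absorbance_file", "spectra_emission_file",
                   "modified_conc_uM", "bands_file", "numerator",
                   "denominator", "n_boot", "seed", "report_Ct_uM",
                   "out_dir", "label")

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line, `#` comments allowed. Unknown keys are
#' rejected.
#'
#' @param path configuration file path.
#' @return Named list of configuration values (all character; the pipeline
#'   coerces).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty run configuration: ", path)
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed configuration line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[[`, character(1), 3L))
  unknown <- setdiff(keys, pipeline_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  stats::setNames(as.list(vals), keys)
}

num_or <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}

#' Run the analysis pipeline
#'
#' Executes every stage for which the configuration names an input file —
#' melting-curve fit, van 't Hoff series, bend angle, titration metrics,
#' excision ratio — writes one delimited report per stage plus a combined
#' summary and a provenance block, and keeps going when an individual stage
#' fails (the failure is recorded and reflected in the return value).
#'
#' @param cfg a named list or a path to a [read_run_config()] file. Keys:
#'   `melting_file` + `melting_Ct_uM`, `series_file`, `mobility_file` +
#'   `mobility_reference`, `spectra_absorbance_file`,
#'   `spectra_emission_file`, `modified_conc_uM`, `bands_file` +
#'   `numerator` + `denominator` (+ `n_boot`, `seed`), `report_Ct_uM`,
#'   `out_dir`, `label`.
#' @return Invisibly, a list with per-stage results and a `failed` character
#'   vector of stages that errored.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- read_run_config(cfg)
  if (!length(cfg)) stop("empty pipeline configuration")
  unknown <- setdiff(names(cfg), pipeline_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  label <- if (is.null(cfg$label)) "run" else cfg$label
  results <- list()
  failed <- character()
  summary_rows <- list()

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      message("stage '", name, "' failed: ", conditionMessage(e))
      failed <<- c(failed, name)
      NULL
    })
  }

  if (!is.null(cfg$melting_file)) {
    results$melt <- stage("melt-fit", {
      curve <- read_melting_table(cfg$melting_file,
                                  Ct = num_or(cfg, "melting_Ct_uM", 20) * 1e-6,
                                  label = label)
      fit <- fit_melting_curve(preprocess_curve(curve))
      message(sprintf("melt-fit: Tm = %.2f C, dH = %.1f kcal/mol, h = %.2f%%%s",
                      fit$tm, fit$params$dH / 1000, fit$hypochromicity,
                      if (fit$converged) "" else " [restarts disagree]"))
      write_report(data.frame(label = label, Tm_C = fit$tm,
                              dH_kcal = fit$params$dH / 1000,
                              dS = fit$params$dS,
                              hypochromicity_pct = fit$hypochromicity,
                              ssr = fit$ssr, converged = fit$converged),
                   file.path(out_dir, "melt_fit.csv"))
      fit
    })
  }

  if (!is.null(cfg$series_file)) {
    results$vanthoff <- stage("vanthoff", {
      ser <- read_series_table(cfg$series_file)
      fit <- fit_vant_hoff(ser)
      row <- summarize_duplex(fit, Ct_report = num_or(cfg, "report_Ct_uM", 20) * 1e-6,
                              label = label)
      message(sprintf("vanthoff: dH = %.1f kcal/mol, dS = %.0f, dG37 = %.2f kcal/mol",
                      row$dH_kcal, row$dS, row$dG37_kcal))
      write_report(row, file.path(out_dir, "vant_hoff.csv"))
      summary_rows$thermo <- row   # assigns in run_pipeline's frame (lazy stage code)
      fit
    })
  }

  if (!is.null(cfg$mobility_file)) {
    results$bend <- stage("bend", {
      lanes <- read_mobility_table(cfg$mobility_file)
      ref <- if (is.null(cfg$mobility_reference)) lanes$lane[1] else cfg$mobility_reference
      rel <- relative_mobility(lanes, ref)
      rows <- do.call(rbind, lapply(which(rel$lane != ref), function(i) {
        b <- bend_angle(rel$ratio[i])
        data.frame(lane = rel$lane[i], ratio = b$ratio,
                   interior_angle_deg = b$interior_angle,
                   deflection_deg = b$deflection)
      }))
      message(sprintf("bend: %s", paste(sprintf("%s %.2f deg", rows$lane,
                                                rows$interior_angle_deg),
                                        collapse = ", ")))
      write_report(rows, file.path(out_dir, "bend.csv"))
      rows
    })
  }

  if (!is.null(cfg$spectra_absorbance_file)) {
    results$titration_abs <- stage("titrate-absorbance", {
      sp <- read_spectra_table(cfg$spectra_absorbance_file, mode = "absorbance",
                               modified_conc = num_or(cfg, "modified_conc_uM", 5.4) * 1e-6)
      eff <- hypochromic_effect(sp, center = 495)
      tr <- a260_trend(sp)
      message(sprintf("titrate: 495 nm hypochromic effect %.1f%% (trend %s)",
                      eff$hypochromic_effect_pct, eff$monotone_flag))
      write_report(data.frame(label = label,
                              effect495_pct = eff$hypochromic_effect_pct,
                              monotone = eff$monotone_flag,
                              a260_line_rss = tr$rss,
                              a260_sublinear = tr$sublinear),
                   file.path(out_dir, "titration_absorbance.csv"))
      list(effect = eff, a260 = tr)
    })
  }

  if (!is.null(cfg$spectra_emission_file)) {
    results$titration_em <- stage("titrate-emission", {
      sp <- read_spectra_table(cfg$spectra_emission_file, mode = "emission",
                               modified_conc = num_or(cfg, "modified_conc_uM", 5.4) * 1e-6)
      q <- quench_fraction(sp)
      message(sprintf("titrate: saturation quench fraction %.3f (trend %s)",
                      q$fractions[length(q$fractions)], q$monotone_flag))
      write_report(data.frame(complement_uM = as.numeric(names(q$fractions)),
                              quench_fraction = as.numeric(q$fractions)),
                   file.path(out_dir, "quench.csv"))
      q
    })
  }

  if (!is.null(cfg$bands_file)) {
    results$excision <- stage("excision", {
      tcs <- read_bands_table(cfg$bands_file)
      num <- cfg$numerator; den <- cfg$denominator
      if (is.null(num) || is.null(den))
        stop("bands analysis needs 'numerator' and 'denominator' substrate labels")
      if (!num %in% names(tcs) || !den %in% names(tcs))
        stop("substrates not found in band table: ", num, " / ", den)
      er <- efficiency_ratio(lapply(tcs[[num]], normalize_timecourse),
                             lapply(tcs[[den]], normalize_timecourse),
                             n_boot = as.integer(num_or(cfg, "n_boot", 2000)),
                             seed = as.integer(num_or(cfg, "seed", 1)))
      message(sprintf("excision: %s/%s summary ratio %.2f [%.2f, %.2f]",
                      num, den, er$summary_ratio, er$ci_low, er$ci_high))
      write_report(data.frame(numerator = num, denominator = den,
                              summary_ratio = er$summary_ratio,
                              ci_low = er$ci_low, ci_high = er$ci_high,
                              n_boot = er$n_boot),
                   file.path(out_dir, "excision.csv"))
      er
    })
  }

  if (!length(results)) stop("configuration names no stage inputs")

  ## combined summary + provenance
  srow <- data.frame(label = label)
  if (!is.null(summary_rows$thermo)) srow <- summary_rows$thermo
  if (!is.null(results$melt)) {
    srow$Tm_fit_C <- results$melt$tm
    srow$hypochromicity_pct <- results$melt$hypochromicity
  }
  if (!is.null(results$bend)) {
    srow$bend_interior_deg <- paste(sprintf("%.2f", results$bend$interior_angle_deg),
                                    collapse = ";")
  }
  if (!is.null(results$titration_abs))
    srow$effect495_pct <- results$titration_abs$effect$hypochromic_effect_pct
  if (!is.null(results$excision))
    srow$excision_ratio <- results$excision$summary_ratio
  write_report(srow, file.path(out_dir, "summary.csv"))
  prov <- c(paste0("duplexfit_version = ",
                   as.character(utils::packageVersion("duplexfit"))),
            paste0("timestamp = ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            paste(names(cfg), unlist(cfg), sep = " = "))
  writeLines(prov, file.path(out_dir, "provenance.txt"))

  results$failed <- failed
  if (length(failed))
    warning("failed stages: ", paste(failed, collapse = ", "))
  invisible(results)
}
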