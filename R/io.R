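## Delimited-text I/O. Comma is the default separator, tab is auto-detected;
## '#' lines are comments; the decimal separator is the dot.

detect_sep <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path)
  if (grepl("\t", lines[1])) "\t" else ","
}

read_delim_checked <- function(path, required, dialect) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, strip.white = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(dialect, " table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in required) {
    if (is.character(df[[col]]) && !col %in% c("lane_label", "substrate", "replicate", "lane")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at data row ", bad[1],
             " of ", path)
      df[[col]] <- v
    }
  }
  df
}

#' Read a stage input table
#'
#' One reader per file dialect, all plain delimited text (comma default, tab
#' auto-detected), `#` comment lines skipped, header row required:
#' \describe{
#'   \item{melting}{columns `temperature_C`, `absorbance`, optional
#'     `reference_absorbance` -> [melting_curve()]}
#'   \item{series}{columns `Ct_uM`, `Tm_C`, optional `Tm_err_C` ->
#'     [concentration_series()]}
#'   \item{spectra}{first column `wavelength_nm`, a column `control`, one
#'     column per sample named by its complement concentration in uM ->
#'     [spectrum_series()]}
#'   \item{bands}{columns `substrate`, `replicate`, `time_min`, `intensity`
#'     -> named list of [excision_timecourse()] replicates per substrate}
#'   \item{mobility}{columns `lane_label`, `band_position_mm` -> lane
#'     `data.frame` for [relative_mobility()]}
#' }
#'
#' @param path file path.
#' @param dialect one of `"melting"`, `"series"`, `"spectra"`, `"bands"`,
#'   `"mobility"`.
#' @param ... metadata passed to the domain constructor (e.g. `Ct`,
#'   `wavelength`, `ramp`, `label` for melting; `mode`, `modified_conc` for
#'   spectra).
#' @return The validated domain object for the target stage.
#' @export
read_table <- function(path, dialect = c("melting", "series", "spectra",
                                         "bands", "mobility"), ...) {
  dialect <- match.arg(dialect)
  switch(dialect,
         melting = read_melting_table(path, ...),
         series = read_series_table(path),
         spectra = read_spectra_table(path, ...),
         bands = read_bands_table(path),
         mobility = read_mobility_table(path))
}

#' @rdname read_table
#' @param Ct total strand concentration, mol/L (melting dialect).
#' @export
read_melting_table <- function(path, Ct, ...) {
  df <- read_delim_checked(path, c("temperature_C", "absorbance"), "melting")
  ref <- if ("reference_absorbance" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$reference_absorbance))
    if (anyNA(v)) stop("non-numeric reference_absorbance in ", path)
    v
  }
  melting_curve(df$temperature_C, df$absorbance, Ct = Ct, reference = ref, ...)
}

#' @rdname read_table
#' @export
read_series_table <- function(path) {
  df <- read_delim_checked(path, c("Ct_uM", "Tm_C"), "series")
  err <- if ("Tm_err_C" %in% names(df)) as.numeric(df$Tm_err_C)
  concentration_series(df$Ct_uM * 1e-6, df$Tm_C, tm_err = err)
}

#' @rdname read_table
#' @param mode spectrum mode (spectra dialect).
#' @param modified_conc fixed modified-strand concentration, mol/L.
#' @export
read_spectra_table <- function(path, mode = "absorbance",
                               modified_conc = 5.4e-6) {
  df <- read_delim_checked(path, c("wavelength_nm", "control"), "spectra")
  sample_cols <- setdiff(names(df), c("wavelength_nm", "control"))
  conc <- suppressWarnings(as.numeric(sample_cols))
  if (!length(sample_cols) || anyNA(conc))
    stop("spectra table needs sample columns named by complement concentration in uM")
  o <- order(conc)
  spectrum_series(df$wavelength_nm,
                  as.matrix(df[, sample_cols[o], drop = FALSE]),
                  conc[o] * 1e-6, df$control, mode = mode,
                  modified_conc = modified_conc)
}

#' @rdname read_table
#' @export
read_bands_table <- function(path) {
  df <- read_delim_checked(path, c("substrate", "replicate", "time_min",
                                   "intensity"), "bands")
  out <- lapply(split(df, df$substrate), function(d) {
    lapply(split(d, d$replicate), function(r) {
      r <- r[order(r$time_min), ]
      excision_timecourse(r$time_min, r$intensity,
                          substrate = r$substrate[1],
                          replicate = r$replicate[1])
    })
  })
  out
}

#' @rdname read_table
#' @export
read_mobility_table <- function(path) {
  df <- read_delim_checked(path, c("lane_label", "band_position_mm"), "mobility")
  data.frame(lane = df$lane_label, position = df$band_position_mm,
             stringsAsFactors = FALSE)
}

#' Write a report table
#'
#' Comma-delimited text with a header row; numbers are written with 12
#' significant digits so reports are reproducible bit-for-bit under a fixed
#' seed and round-trip through the readers.
#'
#' @param df a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated input bundle
#'
#' Emits, for one scenario, the exact file dialects the analysis readers
#' consume — a melting curve, a Tm concentration series, absorbance and
#' emission titration series, an excision band table (both substrates) and a
#' gel lane table — plus `manifest.txt`, a key-value record of the
#' generating ground truth.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if needed).
#' @param Ct melting-curve concentration, mol/L.
#' @return Named character vector of the files written.
#' @export
write_simulated_inputs <- function(cfg, dir, Ct = 20e-6) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) trimws(formatC(x, digits = 12, format = "g"))
  paths <- c()

  curve <- sim_melting_curve(cfg, Ct = Ct)
  p <- file.path(dir, "melting.csv")
  write_report(data.frame(temperature_C = curve$temperature,
                          absorbance = curve$absorbance), p)
  paths["melting"] <- p

  ser <- sim_concentration_series(cfg, tm_sigma = 0)
  p <- file.path(dir, "tm_series.csv")
  write_report(data.frame(Ct_uM = ser$Ct * 1e6, Tm_C = ser$Tm), p)
  paths["series"] <- p

  for (mode in c("absorbance", "emission")) {
    sp <- sim_titration_series(cfg, mode = mode)
    d <- data.frame(wavelength_nm = sp$wavelength, control = sp$control,
                    check.names = FALSE)
    d[sprintf("%g", sp$complement_conc * 1e6)] <- sp$intensities
    p <- file.path(dir, paste0("titration_", mode, ".csv"))
    write_report(d, p)
    paths[paste0("titration_", mode)] <- p
  }

  tcs <- sim_excision_timecourses(cfg)
  rows <- do.call(rbind, lapply(unlist(tcs, recursive = FALSE), function(tc)
    data.frame(substrate = tc$substrate, replicate = tc$replicate,
               time_min = tc$time, intensity = tc$intensity)))
  p <- file.path(dir, "excision_bands.csv")
  write_report(rows, p)
  paths["bands"] <- p

  lanes <- sim_mobility_lanes(cfg)
  p <- file.path(dir, "mobility.csv")
  write_report(data.frame(lane_label = lanes$lane,
                          band_position_mm = lanes$position), p)
  paths["mobility"] <- p

  truth_curve <- attr(curve, "truth")
  man <- c(scenario = cfg$scenario, seed = cfg$seed,
           dH_cal_mol = fmt(cfg$params$dH), dS_cal_molK = fmt(cfg$params$dS),
           tm_C_at_20uM = fmt(truth_curve$tm),
           hypochromicity_pct = fmt(cfg$hypochromicity),
           effect495_pct = fmt(cfg$effect495), quench = fmt(cfg$quench),
           bend_interior_deg = fmt(cfg$bend_interior),
           excision_rate_ratio = fmt(attr(tcs, "truth")$rate_ratio))
  p <- file.path(dir, "manifest.txt")
  writeLines(paste(names(man), man, sep = " = "), p)
  paths["manifest"] <- p
  paths
}
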