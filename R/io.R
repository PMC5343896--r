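## Delimited-text readers/writers for the package's containers, plus a JSON
## serialization of every container (axes + data + metadata).

#' Write a spectral series as delimited text
#'
#' Column 1 is the wavelength (nm); each subsequent column is one condition,
#' with the condition value carried in the header row.
#'
#' @param series a [spectral_series()].
#' @param file output path.
#' @param delim field delimiter, default tab.
#' @return `file`, invisibly.
#' @export
write_spectral_series <- function(series, file, delim = "\t") {
  stopifnot(inherits(series, "spectral_series"))
  df <- data.frame(wavelength = series$wavelengths, series$matrix,
                   check.names = FALSE)
  names(df) <- c("wavelength", format(series$conditions, trim = TRUE,
                                      digits = 15))
  utils::write.table(df, file, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a spectral series from delimited text
#'
#' @param file path written by [write_spectral_series()] (or any delimited
#'   table whose first column is the wavelength and whose remaining column
#'   names are numeric condition values).
#' @param delim field delimiter, default tab.
#' @return a [spectral_series()].
#' @export
read_spectral_series <- function(file, delim = "\t") {
  df <- utils::read.table(file, sep = delim, header = TRUE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  conditions <- as.numeric(names(df)[-1])
  if (anyNA(conditions)) {
    stop("header row must carry numeric condition values", call. = FALSE)
  }
  spectral_series(df[[1]], conditions, as.matrix(df[, -1, drop = FALSE]))
}

#' Write an unfolding curve as delimited text
#'
#' Two columns (`urea_M`, `observable`) preceded by `#`-comment lines
#' recording the probe and the temperature.
#'
#' @param curve an [unfolding_curve()].
#' @param file output path.
#' @param delim field delimiter, default tab.
#' @return `file`, invisibly.
#' @export
write_unfolding_curve <- function(curve, file, delim = "\t") {
  stopifnot(inherits(curve, "unfolding_curve"))
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# probe=%s", curve$probe),
               sprintf("# temperature_K=%.6g", curve$temperature_K)), con)
  utils::write.table(data.frame(urea_M = curve$x, observable = curve$y),
                     con, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an unfolding curve from delimited text
#'
#' @param file path written by [write_unfolding_curve()].
#' @param delim field delimiter, default tab.
#' @return an [unfolding_curve()].
#' @export
read_unfolding_curve <- function(file, delim = "\t") {
  lines <- readLines(file, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  probe <- sub("^#\\s*probe=", "", grep("probe=", meta, value = TRUE)[1])
  tk <- as.numeric(sub("^#\\s*temperature_K=", "",
                       grep("temperature_K=", meta, value = TRUE)[1]))
  if (is.na(probe) || !probe %in% c("far_uv_cd", "fluorescence")) {
    probe <- "far_uv_cd"
  }
  if (is.na(tk)) tk <- .T_DEFAULT_K
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = delim,
                          header = TRUE)
  unfolding_curve(df[[1]], df[[2]], probe = probe, temperature_K = tk)
}

#' Write a thermal melt as delimited text
#'
#' Columns `temperature`, `theta222`, and optionally `pmtv` and `blank`.
#'
#' @param melt a [thermal_melt()].
#' @param file output path.
#' @param delim field delimiter, default tab.
#' @return `file`, invisibly.
#' @export
write_thermal_melt <- function(melt, file, delim = "\t") {
  stopifnot(inherits(melt, "thermal_melt"))
  df <- data.frame(temperature = melt$temperature, theta222 = melt$theta222)
  if (!is.null(melt$pmtv)) df$pmtv <- melt$pmtv
  if (!is.null(melt$blank)) df$blank <- melt$blank
  utils::write.table(df, file, sep = delim, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a thermal melt from delimited text
#'
#' @param file path written by [write_thermal_melt()].
#' @param delim field delimiter, default tab.
#' @return a [thermal_melt()].
#' @export
read_thermal_melt <- function(file, delim = "\t") {
  df <- utils::read.table(file, sep = delim, header = TRUE,
                          fileEncoding = "UTF-8")
  thermal_melt(df$temperature, df$theta222,
               pmtv = df[["pmtv"]], blank = df[["blank"]])
}

## JSON serialization ---------------------------------------------------------

#' Serialize a container to JSON
#'
#' Every container serializes to a JSON object with a `type` tag, its axes,
#' its data, and its metadata; [container_from_json()] inverts the mapping.
#'
#' @param x an [emission_spectrum()], [cd_spectrum()], [spectral_series()],
#'   [unfolding_curve()] or [thermal_melt()].
#' @return a JSON string.
#' @export
container_to_json <- function(x) {
  payload <- if (inherits(x, "emission_spectrum")) {
    list(type = "emission_spectrum", wavelengths = x$wavelengths,
         intensities = x$intensities, condition = x$condition, label = x$label)
  } else if (inherits(x, "cd_spectrum")) {
    list(type = "cd_spectrum", wavelengths = x$wavelengths, signal = x$signal,
         units = x$units, pathlength_cm = x$pathlength_cm,
         conc_mg_ml = x$conc_mg_ml, mean_residue_mass = x$mean_residue_mass,
         label = x$label)
  } else if (inherits(x, "spectral_series")) {
    list(type = "spectral_series", wavelengths = x$wavelengths,
         conditions = x$conditions, matrix = x$matrix)
  } else if (inherits(x, "unfolding_curve")) {
    list(type = "unfolding_curve", x = x$x, y = x$y, probe = x$probe,
         temperature_K = x$temperature_K)
  } else if (inherits(x, "thermal_melt")) {
    list(type = "thermal_melt", temperature = x$temperature,
         theta222 = x$theta222, pmtv = x$pmtv, blank = x$blank)
  } else {
    stop("unsupported container", call. = FALSE)
  }
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Deserialize a container from JSON
#'
#' @param json a JSON string produced by [container_to_json()].
#' @return the reconstructed container.
#' @export
container_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  switch(p$type,
    emission_spectrum = emission_spectrum(p$wavelengths, p$intensities,
                                          condition = p$condition,
                                          label = p$label),
    cd_spectrum = cd_spectrum(p$wavelengths, p$signal, units = p$units,
                              pathlength_cm = p$pathlength_cm,
                              conc_mg_ml = p$conc_mg_ml,
                              mean_residue_mass = p$mean_residue_mass,
                              label = p$label),
    spectral_series = spectral_series(p$wavelengths, p$conditions, p$matrix),
    unfolding_curve = unfolding_curve(p$x, p$y, probe = p$probe,
                                      temperature_K = p$temperature_K),
    thermal_melt = thermal_melt(p$temperature, p$theta222,
                                pmtv = p$pmtv, blank = p$blank),
    stop("unknown container type: ", p$type, call. = FALSE)
  )
}
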