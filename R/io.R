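#' Read and write bending curves as CSV
#'
#' Columns: optional time_s, displacement_mm, force_N.
#'
#' @param curve an [fd_curve()]
#' @param path file path
#' @return `read_bending_csv` returns an `fd_curve`
#' @export
write_bending_csv <- function(curve, path) {
  df <- data.frame(displacement_mm = curve$displacement,
                   force_N = curve$force)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bending_csv
#' @param sampling_rate Hz, used when no time column is present
#' @export
read_bending_csv <- function(path, sampling_rate = 100) {
  df <- read.csv(path)
  if (!all(c("displacement_mm", "force_N") %in% names(df)))
    stop_bonemech("bending CSV needs displacement_mm and force_N columns")
  if ("time_s" %in% names(df) && nrow(df) > 1)
    sampling_rate <- 1 / median(diff(df$time_s))
  fd_curve(df$displacement_mm, df$force_N, sampling_rate)
}

#' Read and write indentation curves as CSV
#'
#' Columns: time_s, depth_nm, load_uN (+ optional segment).
#'
#' @param curve indent data.frame (time, depth, load, optional segment)
#' @param path file path
#' @return `read_indent_csv` returns a data.frame(time, depth, load,
#'   segment?)
#' @export
write_indent_csv <- function(curve, path) {
  df <- data.frame(time_s = curve$time, depth_nm = curve$depth,
                   load_uN = curve$load)
  if (!is.null(curve$segment)) df$segment <- curve$segment
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indent_csv
#' @export
read_indent_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "depth_nm", "load_uN")
  if (!all(need %in% names(df)))
    stop_bonemech("indent CSV needs columns ", paste(need, collapse = ", "))
  out <- data.frame(time = df$time_s, depth = df$depth_nm, load = df$load_uN,
                    stringsAsFactors = FALSE)
  if ("segment" %in% names(df)) out$segment <- df$segment
  out
}

#' Read and write Raman spectra as two-column text
#'
#' Tab-separated wavenumber / intensity, the common instrument export.
#'
#' @param spectrum a `raman_spectrum`
#' @param path file path
#' @return `read_spectrum_txt` returns a `raman_spectrum`
#' @export
write_spectrum_txt <- function(spectrum, path) {
  write.table(data.frame(spectrum$wavenumber, spectrum$intensity), path,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_txt
#' @export
read_spectrum_txt <- function(path) {
  df <- read.table(path, sep = "", header = FALSE)
  if (ncol(df) == 1)
    df <- read.table(path, sep = ",", header = FALSE)
  raman_spectrum(df[[1]], df[[2]])
}

#' Write a ground-truth JSON sidecar
#'
#' Written next to a generated raw file with the `.truth.json` suffix
#' replacing the extension, so analyses can be checked against the
#' generating truth.
#'
#' @param truth list-like truth object
#' @param data_path path of the raw data file the truth belongs to
#' @return the sidecar path, invisibly
#' @export
write_truth_sidecar <- function(truth, data_path) {
  path <- paste0(sub("\\.[^.]+$", "", data_path), ".truth.json")
  clean <- truth
  class(clean) <- NULL
  clean <- lapply(clean, function(x) if (is.data.frame(x)) x else unclass(x))
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_sidecar
#' @export
read_truth_sidecar <- function(data_path) {
  path <- if (grepl("\\.truth\\.json$", data_path)) data_path
  else paste0(sub("\\.[^.]+$", "", data_path), ".truth.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
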