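#' Read and write the standard tabular formats
#'
#' All tabular I/O is comma-separated with a mandatory header; units are
#' carried in the column names (MHz, ppm, s^-1, ns, Hz). Rate tables have
#' columns `methyl_id, coherence, field_MHz, rate, err`; CPMG tables
#' `methyl_id, experiment, field_MHz, nu_cpmg_Hz, Reff, err` (optionally
#' `T_relax_s`); peak lists `methyl_id, wH_ppm, wC_ppm` (optionally
#' `residue_type`); CSA tables `methyl_id, dSigmaC_ppm, dSigmaH_ppm,
#' s2tau_ns`. Missing required columns raise an error naming the file and the
#' columns.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return the data.frame (readers) or `invisible(path)` (writers).
#' @name table_io
NULL

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed CSV '", path, "': ", conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  num <- setdiff(required, c("methyl_id", "coherence", "experiment",
                             "residue_type", "cluster_id"))
  for (cc in num) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))
      stop("'", path, "' column '", cc, "' is not numeric (first bad row: ",
           if (length(bad)) bad[1] + 1L else "?", " counting the header)")
    }
  }
  df
}

#' @rdname table_io
#' @export
read_rate_table <- function(path) {
  read_checked_csv(path, c("methyl_id", "coherence", "field_MHz", "rate",
                           "err"))
}

#' @rdname table_io
#' @export
write_rate_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_cpmg_table <- function(path) {
  read_checked_csv(path, c("methyl_id", "experiment", "field_MHz",
                           "nu_cpmg_Hz", "Reff", "err"))
}

#' @rdname table_io
#' @export
write_cpmg_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_peak_list <- function(path) {
  read_checked_csv(path, c("methyl_id", "wH_ppm", "wC_ppm"))
}

#' @rdname table_io
#' @export
read_csa_table <- function(path) {
  read_checked_csv(path, c("methyl_id", "dSigmaC_ppm", "dSigmaH_ppm",
                           "s2tau_ns"))
}

#' Plain-text spectrum grid format
#'
#' One file per relaxation delay: comment header lines carry the delay and
#' the ppm axes, followed by the intensity matrix (rows = 1H axis points,
#' whitespace-separated).
#'
#' @param mat intensity matrix (rows = `wH_ppm`).
#' @param wH_ppm,wC_ppm axes in ppm.
#' @param delay relaxation delay in seconds.
#' @param path file path.
#' @return `write_spectrum_grid` returns `invisible(path)`;
#'   `read_spectrum_grid` a list with `mat`, `wH_ppm`, `wC_ppm`, `delay`.
#' @export
write_spectrum_grid <- function(mat, wH_ppm, wC_ppm, delay, path) {
  stopifnot(nrow(mat) == length(wH_ppm), ncol(mat) == length(wC_ppm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# delay_s", format(delay, digits = 17)),
    paste("# wH_ppm", paste(format(wH_ppm, digits = 17), collapse = " ")),
    paste("# wC_ppm", paste(format(wC_ppm, digits = 17), collapse = " "))),
    con)
  utils::write.table(mat, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_grid
#' @export
read_spectrum_grid <- function(path) {
  lines <- readLines(path, n = 3L)
  parse_hdr <- function(prefix) {
    ln <- lines[startsWith(lines, paste0("# ", prefix))]
    if (!length(ln)) stop("'", path, "' missing header line '# ", prefix, "'")
    as.numeric(strsplit(sub(paste0("^# ", prefix, " +"), "", ln[1]),
                        " +")[[1]])
  }
  delay <- parse_hdr("delay_s")
  wH <- parse_hdr("wH_ppm")
  wC <- parse_hdr("wC_ppm")
  mat <- as.matrix(utils::read.table(path, skip = 3L))
  dimnames(mat) <- NULL
  if (nrow(mat) != length(wH) || ncol(mat) != length(wC))
    stop("'", path, "' matrix dimensions do not match the axis headers")
  list(mat = mat, wH_ppm = wH, wC_ppm = wC, delay = delay)
}

#' Read a key-value run configuration file
#'
#' INI-style sections (`[constants]`, `[grid]`, ...) of `key = value` pairs;
#' values are parsed as numeric where possible. The `[constants]` section can
#' be passed to [nmr_constants()] via `do.call`.
#'
#' @param path file path.
#' @return named list of sections, each a named list of values.
#' @examples
#' \dontrun{
#' cfg <- read_run_config("run.cfg")
#' cst <- do.call(nmr_constants, cfg$constants)
#' }
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- "default"
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("config line ", i, " is not 'key = value': ", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[section]][[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Ground-truth manifest serialisation
#'
#' Writes/reads a [ground_truth()] object as JSON so that synthetic datasets
#' always travel with their generating parameters.
#'
#' @param truth a [ground_truth()].
#' @param path file path.
#' @return `write_manifest` returns `invisible(path)`; `read_manifest` a
#'   [ground_truth()].
#' @export
write_manifest <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(list(methyls = truth$methyls,
                            clusters = truth$clusters),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(as.data.frame(obj$methyls), as.data.frame(obj$clusters))
}
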