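# Delimited-text input/output.  Dialect is fixed: comma separator, "."
# decimal mark, mandatory header row, UTF-8.  Writers emit 17
# significant digits so numeric columns round-trip bit-exactly.

#' Read a delimited numeric table with a fixed schema
#'
#' Comma-separated, "." decimal mark, header required.  Column names
#' must match the schema exactly (required columns first, optional ones
#' may follow).  Any malformed row -- wrong field count (as produced,
#' e.g., by locale-style decimal commas) or a non-numeric field -- is
#' rejected with its line number.
#'
#' @param path File path.
#' @param columns Character vector of required column names, in order.
#' @param optional Character vector of optional trailing column names.
#' @return data.frame with numeric columns.
#' @export
read_table <- function(path, columns, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(path, ": empty file")
  hdr <- trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  want_min <- length(columns)
  ok_hdr <- length(hdr) >= want_min &&
    identical(hdr[seq_len(want_min)], columns) &&
    all(hdr[-seq_len(want_min)] %in% optional)
  if (!ok_hdr)
    stop(sprintf("%s: header is '%s' but expected '%s'%s", path,
                 paste(hdr, collapse = ","),
                 paste(columns, collapse = ","),
                 if (length(optional))
                   paste0(" (optional: ",
                          paste(optional, collapse = ","), ")") else ""))
  ncol_file <- length(hdr)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1L]])
    if (length(f) != ncol_file)
      stop(sprintf(
        "%s: line %d has %d fields, expected %d (decimal commas are not supported; use '.')",
        path, i, length(f), ncol_file))
    v <- suppressWarnings(as.numeric(f))
    bad <- which(is.na(v) & !(f %in% c("NA", "NaN")))
    if (length(bad))
      stop(sprintf("%s: line %d: cannot parse '%s' as a number",
                   path, i, f[bad[1L]]))
    v
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- hdr
  out
}

#' Write a numeric table in the package dialect
#'
#' @param df data.frame of numeric columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    body <- apply(vapply(df, function(col)
      ifelse(is.na(col), "NA", sprintf("%.17g", as.numeric(col))),
      character(nrow(df))), 1L, paste, collapse = ",")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a progress curve (`time_s,a340`)
#' @param path File path.
#' @param ... Metadata passed to [progress_curve()] (`substrate_conc`,
#'   `cofactor_conc`, `enzyme_conc`, `label`).
#' @return A [progress_curve()].
#' @export
read_progress_curve <- function(path, ...) {
  d <- read_table(path, c("time_s", "a340"))
  progress_curve(d$time_s, d$a340, ...)
}

#' Read a lambda series (`dhf_M,lambda_per_s[,lambda_err_per_s]`)
#' @param path File path.
#' @param temperature Kelvin.
#' @return A [lambda_series()].
#' @export
read_lambda_series <- function(path, temperature = 296.15) {
  d <- read_table(path, c("dhf_M", "lambda_per_s"),
                  optional = "lambda_err_per_s")
  lambda_series(d$dhf_M, d$lambda_per_s, d$lambda_err_per_s, temperature)
}

#' Read a denaturation curve (`guhcl_M,fluorescence`)
#' @param path File path.
#' @param ligand_conc Molar NADPH present.
#' @param temperature Kelvin.
#' @return A [denaturation_curve()].
#' @export
read_denaturation_curve <- function(path, ligand_conc = 0,
                                    temperature = 296.15) {
  d <- read_table(path, c("guhcl_M", "fluorescence"))
  denaturation_curve(d$guhcl_M, d$fluorescence, ligand_conc, temperature)
}

#' Read a melt curve (`temp_C,fluorescence`)
#' @param path File path.
#' @param label Sample label.
#' @return A [melt_curve()].
#' @export
read_melt_curve <- function(path, label = "") {
  d <- read_table(path, c("temp_C", "fluorescence"))
  melt_curve(d$temp_C, d$fluorescence, label)
}

#' Read polarized decays (`t_ns,counts_parallel,counts_perpendicular`)
#' @param path File path.
#' @param ... Passed to [anisotropy_decay()] (`G`, backgrounds).
#' @return An [anisotropy_decay()].
#' @export
read_anisotropy_decay <- function(path, ...) {
  d <- read_table(path, c("t_ns", "counts_parallel",
                          "counts_perpendicular"))
  anisotropy_decay(d$t_ns, d$counts_parallel, d$counts_perpendicular, ...)
}
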