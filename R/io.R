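#' Write a multi-channel recording to disk
#'
#' Two dialects: `"csv"` — plain text with a `# rate_hz=<value>` metadata
#' line, a header of channel labels, and one row per time point (values at
#' 17 significant digits, lossless to ~1e-16 relative); `"rds"` — R's
#' binary serialisation of the long tibble, bit-exact on round trip.
#'
#' @param data Long recording tibble (`time`, `channel`, `value`).
#' @param path Output file.
#' @param rate Sampling rate in Hz; taken from the `rate` attribute or
#'   inferred when omitted.
#' @param format `"csv"` (default) or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(data, path, rate = NULL, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (is.null(rate)) {
    rate <- attr(data, "rate")
    if (is.null(rate)) rate <- infer_rate(data)
  }
  if (format == "rds") {
    attr(data, "rate") <- rate
    saveRDS(data, path)
    return(invisible(path))
  }
  Y <- as_series_matrix(data)
  labels <- rownames(Y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.17g", rate), con)
  writeLines(paste(labels, collapse = ","), con)
  body <- apply(t(Y), 1, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a multi-channel recording
#'
#' Inverse of [write_recording()]. Text files are validated strictly:
#' missing rate metadata, ragged rows, non-numeric cells and non-finite
#' values all raise descriptive parse errors, and a header-only file is
#' reported as an empty recording.
#'
#' @param path File written by [write_recording()] (`.rds` files are
#'   detected by extension).
#' @return A long recording tibble with a `rate` attribute.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    out <- readRDS(path)
    if (!is.data.frame(out) || is.null(attr(out, "rate"))) {
      abort("rds recording must be a tibble with a `rate` attribute")
    }
    return(out)
  }
  lines <- readLines(path)
  if (length(lines) < 1 || !grepl("^#\\s*rate_hz=", lines[[1]])) {
    abort("missing `# rate_hz=` metadata line")
  }
  rate <- suppressWarnings(as.numeric(sub("^#\\s*rate_hz=", "", lines[[1]])))
  if (is.na(rate) || rate <= 0) abort("unparseable sampling rate in metadata line")
  if (length(lines) < 2) abort("missing channel header line")
  labels <- strsplit(lines[[2]], ",", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0) abort("empty recording: header but no samples")
  q <- length(labels)
  cells <- strsplit(body, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != q)) {
    bad <- which(widths != q)[[1]]
    abort(sprintf("ragged row %d: expected %d fields, found %d",
                  bad, q, widths[[bad]]))
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[[1]]
    abort(sprintf("non-numeric cell at row %d, column %d",
                  (flat - 1) %/% q + 1, (flat - 1) %% q + 1))
  }
  if (any(!is.finite(vals))) {
    flat <- which(!is.finite(vals))[[1]]
    abort(sprintf("non-finite value at row %d, column %d",
                  (flat - 1) %/% q + 1, (flat - 1) %% q + 1))
  }
  Y <- t(matrix(vals, nrow = q))          # time x channels -> transpose later
  samples <- t(Y)
  rownames(samples) <- labels
  out <- series_to_tibble(samples, rate = rate, channels = labels)
  attr(out, "rate") <- rate
  out
}

#' Write change points as delimited text
#'
#' @param cp_tbl Tibble from [detect_change_points()] (optionally with a
#'   `phase` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_change_points <- function(cp_tbl, path) {
  utils::write.csv(as.data.frame(cp_tbl), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serialises lists / tibbles (e.g. a [reconstruction_report()] or the
#' audit trail of a [select_ns()] run) to pretty-printed JSON at full
#' numeric precision.
#'
#' @param report A list or data frame.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", always_decimal = FALSE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (inherits(x, "era_realization")) {
    x <- list(A = x$A, B = x$B, C = x$C, r = x$r, s = x$s, q = x$q, p = x$p,
              numerical_rank = x$numerical_rank,
              singular_values = x$singular_values)
  }
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Serialise / restore a realization as JSON
#'
#' Lossless round trip of the reduced `(A, B, C)` triple with its shape
#' metadata.
#'
#' @param realization An [era_realize()] result.
#' @param path JSON path.
#' @return [write_realization()] returns `path` invisibly;
#'   [read_realization()] returns the `era_realization`.
#' @export
write_realization <- function(realization, path) {
  stopifnot(inherits(realization, "era_realization"))
  jsonlite::write_json(
    list(A = realization$A, B = realization$B, C = realization$C,
         r = realization$r, s = realization$s, q = realization$q,
         p = realization$p, numerical_rank = realization$numerical_rank,
         singular_values = realization$singular_values),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_realization
#' @export
read_realization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(A = matrix(x$A, x$r, x$r), B = matrix(x$B, x$r, x$p),
         C = matrix(x$C, x$q, x$r), r = x$r, s = x$s, q = x$q, p = x$p,
         singular_values = x$singular_values,
         numerical_rank = x$numerical_rank),
    class = "era_realization"
  )
}
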