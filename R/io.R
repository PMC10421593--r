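# Delimited-text readers/writers.  Time series travel as tab-separated
# columns with a one-line header (optionally preceded by '#' provenance
# comments); parameter sets as `key = value` config files.  Times are ms,
# potentials mV, currents normalized.

#' Write a trace (or paired recording) to delimited text
#'
#' Two columns `time_ms` and `V_mV`/`I_norm` (three columns `time_ms`,
#' `V_soma_mV`, `V_bouton_mV` for paired recordings, with the distance in a
#' `.meta` sidecar), tab-separated, one header line, values at 9 significant
#' digits.  Optional `#`-prefixed provenance lines precede the header.
#'
#' @param x A trace or [paired_recording()].
#' @param path Output file.
#' @param provenance Optional character vector written as `# ` comments.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  if (inherits(x, "paired_recording")) {
    writeLines("time_ms\tV_soma_mV\tV_bouton_mV", con)
    tt <- trace_time(x$soma)
    writeLines(sprintf("%.9g\t%.9g\t%.9g", tt, x$soma$V, x$bouton$V), con)
    writeLines(sprintf("distance_um = %.9g", x$distance_um),
               paste0(path, ".meta"))
  } else if (inherits(x, "ephys_trace")) {
    nm <- if (inherits(x, "voltage_trace")) "V_mV" else "I_norm"
    writeLines(sprintf("time_ms\t%s", nm), con)
    writeLines(sprintf("%.9g\t%.9g", trace_time(x), trace_values(x)), con)
  } else {
    cp_stop("`x` must be a trace or a paired_recording.")
  }
  invisible(path)
}

#' Read a trace from delimited text
#'
#' Parses the dialect written by [write_trace()]: an optional block of `#`
#' comments, one header line, then tab-separated numeric columns.  Sampling
#' uniformity is validated (maximum jitter below 1% of the sample interval)
#' and the trace kind is taken from the header unless `expected_kind`
#' overrides it.
#'
#' @param path Input file.
#' @param expected_kind `"auto"`, `"voltage"`, `"current"` or `"paired"`.
#' @param distance_um Distance for paired files (overrides the sidecar).
#' @return A [voltage_trace()], [current_trace()] or [paired_recording()].
#' @export
read_trace <- function(path, expected_kind = c("auto", "voltage", "current",
                                               "paired"),
                       distance_um = NULL) {
  expected_kind <- match.arg(expected_kind)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) cp_stop("empty file.", "cavprime_parse_error")
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!anyNA(suppressWarnings(as.numeric(hdr)))) {
    cp_stop("missing header line (first row is numeric).",
            "cavprime_parse_error")
  }
  nc <- length(hdr)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != nc)
  if (length(bad)) {
    cp_stop(sprintf("ragged row at data line %d.", bad[1]),
            "cavprime_parse_error")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = nc,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    cp_stop(sprintf("non-numeric value at data line %d.", bad),
            "cavprime_parse_error")
  }
  tt <- m[, 1]
  dts <- diff(tt)
  dt <- median(dts)
  if (dt <= 0 || max(abs(dts - dt)) > 0.01 * dt) {
    bad <- which(abs(dts - dt) > 0.01 * dt)[1]
    cp_stop(sprintf("non-uniform sampling at data line %d.",
                    ifelse(is.na(bad), 1L, bad + 1L)),
            "cavprime_parse_error")
  }
  if (nc == 3 || expected_kind == "paired") {
    if (nc != 3) {
      cp_stop("paired recordings need 3 columns.", "cavprime_parse_error")
    }
    if (is.null(distance_um)) {
      meta <- paste0(path, ".meta")
      if (!file.exists(meta)) {
        cp_stop("no `distance_um` given and no .meta sidecar found.",
                "cavprime_parse_error")
      }
      distance_um <- read_config(meta)$distance_um
    }
    return(paired_recording(voltage_trace(m[, 2], dt, t0 = tt[1]),
                            voltage_trace(m[, 3], dt, t0 = tt[1]),
                            distance_um))
  }
  kind <- if (expected_kind != "auto") {
    expected_kind
  } else if (grepl("^V", hdr[2])) "voltage" else "current"
  if (kind == "voltage") {
    voltage_trace(m[, 2], dt, t0 = tt[1])
  } else {
    current_trace(m[, 2], dt, t0 = tt[1])
  }
}

#' Read and write `key = value` configuration files
#'
#' Blank lines and `#` comments are ignored; values that parse as numbers
#' become numeric.
#'
#' @param path File path.
#' @return `read_config()`: a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      cp_stop(sprintf("malformed config line: `%s`.", ln),
              "cavprime_parse_error")
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param x Named list of scalar values.
#' @export
write_config <- function(x, path) {
  fmt <- vapply(x, function(v) {
    if (is.numeric(v)) sprintf("%.9g", v) else as.character(v)
  }, character(1))
  writeLines(sprintf("%s = %s", names(x), fmt), path)
  invisible(path)
}

#' Read Cav model parameters from a config file
#'
#' The file holds `key = value` pairs mirroring the [cav_params()] fields;
#' missing keys take the defaults.
#'
#' @param path Config file path.
#' @return A [cav_params()] object.
#' @export
read_cav_params <- function(path) {
  cfg <- read_config(path)
  known <- c("V_Cav50", "alpha", "k_on", "k_off", "E_Ca", "dt")
  do.call(cav_params, cfg[intersect(names(cfg), known)])
}
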