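#' Construct a time-series trace
#'
#' The basic container of the package: a sampled signal on a strictly
#' increasing time base, tagged with the kind of measurement and free-form
#' metadata (genotype, actinic intensity, DCMU flag, ...). Time is always in
#' seconds internally; readers convert at the boundary.
#'
#' @param time Numeric vector of sampling times in seconds, strictly
#'   increasing, length >= 4 (shorter traces are accepted only with
#'   `strict = FALSE`, e.g. for toy files).
#' @param value Numeric signal values. Fluorescence and Fv/Fm traces must be
#'   non-negative; `pigment` traces must lie in `[0, 1]`.
#' @param kind One of `"induction"`, `"pam"`, `"pigment"`, `"fvfm_course"`,
#'   `"ecs_point_set"`.
#' @param meta Named list of metadata (e.g. `genotype`, `actinic`, `dcmu`,
#'   `temperature`, `unit`).
#' @param strict If `TRUE` (default) enforce the minimum length of 4.
#' @return An object of class `fluor_trace`: a list with elements `time`,
#'   `value`, `kind`, `meta`.
#' @examples
#' tr <- fluor_trace(seq(0, 1, 0.1), seq(0, 1, 0.1)^2, kind = "induction",
#'                   meta = list(genotype = "WT"))
#' tr
#' @export
fluor_trace <- function(time, value, kind = c("induction", "pam", "pigment",
                                              "fvfm_course", "ecs_point_set"),
                        meta = list(), strict = TRUE) {
  kind <- match.arg(kind)
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value))
    stop("time and value must have equal length")
  if (strict && length(time) < 4L)
    stop("a trace needs at least 4 samples")
  if (anyNA(time) || anyNA(value))
    stop("trace contains missing values")
  dt <- diff(time)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    stop(sprintf("non-increasing time at row %d (t[%d] = %g, t[%d] = %g)",
                 i + 1L, i, time[i], i + 1L, time[i + 1L]))
  }
  if (kind %in% c("induction", "pam", "fvfm_course") && any(value < 0))
    stop("fluorescence values must be >= 0")
  if (kind == "pigment" && (any(value < 0) || any(value > 1)))
    stop("mole fractions must lie in [0, 1]")
  structure(list(time = time, value = value, kind = kind,
                 meta = as.list(meta)),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> kind=%s, n=%d, span=[%g, %g] s\n",
              x$kind, length(x$time), x$time[1L], x$time[length(x$time)]))
  if (length(x$meta)) {
    kv <- vapply(names(x$meta), function(k)
      sprintf("%s=%s", k, format(x$meta[[k]])), character(1))
    cat("  meta:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(time = x$time, value = x$value)
}

#' Read a trace from a delimited text file
#'
#' Expects two numeric columns (time, value); comment lines starting with
#' `#` may carry `key=value` metadata. Comma or whitespace/tab separation is
#' autodetected. A `time_unit` metadata entry of `ms` or `min` triggers
#' conversion to seconds at read time.
#'
#' @param path Path to an existing file.
#' @param kind Trace kind passed to [fluor_trace()].
#' @return A validated [fluor_trace()].
#' @export
read_trace <- function(path, kind = "induction") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  is_meta <- startsWith(trimws(raw), "#")
  meta <- parse_meta_lines(raw[is_meta])
  body <- raw[!is_meta]
  if (!length(body)) stop("format error: no data rows in ", path)
  sep <- if (grepl(",", body[1L], fixed = TRUE)) "," else ""
  df <- utils::read.table(text = body, sep = sep, header = looks_like_header(body[1L], sep),
                          strip.white = TRUE)
  if (ncol(df) < 2L || nrow(df) == 0L)
    stop("format error: need two numeric columns in ", path)
  tm <- suppressWarnings(as.numeric(df[[1L]]))
  vl <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(tm) || anyNA(vl)) stop("format error: non-numeric data in ", path)
  unit <- meta$time_unit %||% "s"
  fac <- switch(unit, s = 1, ms = 1e-3, min = 60,
                stop("unknown time_unit: ", unit))
  meta$time_unit <- NULL
  fluor_trace(tm * fac, vl, kind = kind, meta = meta, strict = FALSE)
}

#' Write a trace to a delimited text file
#'
#' Metadata are stored as `# key=value` comment lines; the body is a
#' two-column comma-separated table `time,value` with time in seconds at
#' full double precision.
#'
#' @param trace A [fluor_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluor_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", trace$kind), con)
  for (k in names(trace$meta))
    writeLines(sprintf("# %s=%s", k, format(trace$meta[[k]], digits = 17)), con)
  writeLines("time,value", con)
  writeLines(paste(format(trace$time, digits = 17, trim = TRUE, scientific = FALSE),
                   format(trace$value, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    k <- trimws(sub("=.*$", "", ln))
    v <- trimws(sub("^[^=]*=", "", ln))
    vn <- suppressWarnings(as.numeric(v))
    meta[[k]] <- if (!is.na(vn)) vn else v
  }
  # 'kind' is structural, not user metadata
  meta[setdiff(names(meta), "kind")]
}

looks_like_header <- function(line, sep) {
  fields <- if (identical(sep, ",")) strsplit(line, ",")[[1L]] else
    strsplit(trimws(line), "\\s+")[[1L]]
  any(is.na(suppressWarnings(as.numeric(fields))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a saturating-pulse protocol
#'
#' Describes a PAM measuring session: actinic light segments, saturating
#' pulse times, and dark-relaxation windows.
#'
#' @param actinic Data frame with columns `start`, `end` (seconds) and
#'   `intensity` (umol photons m-2 s-1); segments must be ordered and
#'   non-overlapping.
#' @param pulses Numeric vector of saturating-pulse times (seconds).
#' @param dark Data frame with columns `start`, `end` for dark-relaxation
#'   windows (may be empty).
#' @param pulse_duration Width of a saturating pulse in seconds (used by the
#'   level extractor to place its windows).
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(actinic, pulses, dark = NULL, pulse_duration = 0.8) {
  actinic <- as.data.frame(actinic)
  stopifnot(all(c("start", "end", "intensity") %in% names(actinic)))
  if (is.null(dark)) dark <- data.frame(start = numeric(0), end = numeric(0))
  dark <- as.data.frame(dark)
  if (nrow(actinic) > 1L) {
    o <- order(actinic$start)
    actinic <- actinic[o, , drop = FALSE]
  }
  structure(list(actinic = actinic, pulses = sort(as.numeric(pulses)),
                 dark = dark, pulse_duration = pulse_duration),
            class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<pulse_protocol> %d actinic segment(s), %d pulse(s), %d dark window(s)\n",
              nrow(x$actinic), length(x$pulses), nrow(x$dark)))
  invisible(x)
}

#' Validate a protocol against a trace
#'
#' Report-based validation: returns a character vector of violations
#' (overlapping actinic segments, pulses outside the recorded span).
#' An empty report means the protocol is consistent with the trace.
#'
#' @param protocol A [pulse_protocol()].
#' @param trace A [fluor_trace()].
#' @return Character vector of human-readable violations (length 0 if valid).
#' @export
validate_protocol <- function(protocol, trace) {
  stopifnot(inherits(protocol, "pulse_protocol"), inherits(trace, "fluor_trace"))
  report <- character(0)
  seg <- protocol$actinic
  if (nrow(seg) > 1L) {
    for (i in seq_len(nrow(seg) - 1L)) {
      if (seg$end[i] > seg$start[i + 1L])
        report <- c(report, sprintf(
          "actinic segments %d and %d overlap ([%g,%g] vs [%g,%g])",
          i, i + 1L, seg$start[i], seg$end[i], seg$start[i + 1L], seg$end[i + 1L]))
    }
  }
  if (any(seg$end <= seg$start))
    report <- c(report, "actinic segment with end <= start")
  span <- range(trace$time)
  out <- protocol$pulses < span[1L] | protocol$pulses > span[2L]
  if (any(out))
    report <- c(report, sprintf("pulse at t=%g s outside recorded span [%g, %g]",
                                protocol$pulses[out], span[1L], span[2L]))
  report
}

#' Write / read a protocol as JSON
#' @param protocol A [pulse_protocol()].
#' @param path File path.
#' @return `read_protocol` returns a [pulse_protocol()]; `write_protocol`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pulse_protocol(as.data.frame(x$actinic), x$pulses,
                 dark = if (length(x$dark$start)) as.data.frame(x$dark) else NULL,
                 pulse_duration = x$pulse_duration %||% 0.8)
}

#' Construct a pigment (xanthophyll) time-course profile
#'
#' Holds violaxanthin (V), antheraxanthin (A) and zeaxanthin (Z) amounts per
#' time point, plus optional chlorophyll columns. Quantities must be
#' non-negative and the VAZ pool must be positive wherever a de-epoxidation
#' index is to be computed.
#'
#' @param time Sampling times (seconds), strictly increasing.
#' @param V,A,Z Pigment amounts (mole fractions or raw amounts; unit tagged
#'   in `meta$unit`).
#' @param meta Named metadata list (genotype, unit, VAZ per 100 Chl, ...).
#' @return Object of class `pigment_profile` with a data.frame `data`.
#' @export
pigment_profile <- function(time, V, A, Z, meta = list()) {
  time <- as.numeric(time)
  if (any(diff(time) <= 0)) stop("non-increasing time in pigment profile")
  if (any(c(V, A, Z) < 0)) stop("pigment amounts must be >= 0")
  structure(list(data = data.frame(time = time, V = V, A = A, Z = Z),
                 meta = as.list(meta)),
            class = "pigment_profile")
}

#' @export
print.pigment_profile <- function(x, ...) {
  cat(sprintf("<pigment_profile> n=%d, span=[%g, %g] s\n",
              nrow(x$data), min(x$data$time), max(x$data$time)))
  invisible(x)
}

#' Read / write a pigment profile as delimited text (columns t,V,A,Z)
#' @param path File path.
#' @param profile A [pigment_profile()].
#' @return `read_pigments` returns a [pigment_profile()].
#' @export
read_pigments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  is_meta <- startsWith(trimws(raw), "#")
  meta <- parse_meta_lines(raw[is_meta])
  df <- utils::read.csv(text = raw[!is_meta])
  names(df)[1L] <- "time"
  pigment_profile(df$time, df$V, df$A, df$Z, meta = meta)
}

#' @rdname read_pigments
#' @export
write_pigments <- function(profile, path) {
  stopifnot(inherits(profile, "pigment_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(profile$meta))
    writeLines(sprintf("# %s=%s", k, format(profile$meta[[k]], digits = 17)), con)
  utils::write.csv(profile$data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
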