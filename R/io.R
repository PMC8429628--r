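#' Write a trace in Axon Text Format (ATF 1.0)
#'
#' Writes the trace as an ATF 1.0 file: the `ATF 1.0` signature, a
#' header-count/column-count line, quoted optional-header records carrying
#' rate, voltage and metadata, a column-title line, and tab-separated
#' Time (s) / Current (pA) rows. Times are written with 6 decimals,
#' currents with 4.
#'
#' @param trace A `current_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atf <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  meta <- trace$meta
  hdr <- c(
    sprintf("\"SampleRate=%g\"", trace$rate),
    sprintf("\"HoldingVoltage=%g\"", trace$voltage),
    sprintf("\"StartTime=%g\"", trace$t0),
    vapply(names(meta), function(k) {
      sprintf("\"Comment %s=%s\"", k, as.character(meta[[k]]))
    }, character(1), USE.NAMES = FALSE)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ATF\t1.0",
               sprintf("%d\t2", length(hdr)),
               hdr,
               "\"Time (s)\"\t\"Current (pA)\""), con)
  if (length(trace$samples)) {
    tt <- trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
    writeLines(sprintf("%.6f\t%.4f", tt, trace$samples), con)
  }
  invisible(path)
}

#' Write a trace in the package's TSV dialect
#'
#' Two tab-separated columns (`time_s`, `current_pA`) preceded by
#' `#`-prefixed header keys (`rate`, `voltage`, `t0`, and `meta.*`).
#'
#' @param trace A `current_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rate: %g", trace$rate),
    sprintf("# voltage: %g", trace$voltage),
    sprintf("# t0: %g", trace$t0),
    vapply(names(trace$meta), function(k) {
      sprintf("# meta.%s: %s", k, as.character(trace$meta[[k]]))
    }, character(1), USE.NAMES = FALSE),
    "time_s\tcurrent_pA"), con)
  if (length(trace$samples)) {
    tt <- trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
    writeLines(sprintf("%.6f\t%.4f", tt, trace$samples), con)
  }
  invisible(path)
}

#' Read a current trace from file
#'
#' Reads either an ATF 1.0 file or the package's TSV dialect; the format
#' is sniffed from the first line. The sampling rate is taken from the
#' header when present, otherwise inferred from the time column, which
#' must be uniform.
#'
#' @param path Input file path.
#' @return A `current_trace`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) && startsWith(first, "ATF")) read_atf(path)
  else read_trace_tsv_file(path)
}

read_atf <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "ATF")) {
    stop("parse error at line 1: not an ATF signature: ", lines[1])
  }
  dims <- strsplit(lines[2], "\t")[[1]]
  n_hdr <- suppressWarnings(as.integer(dims[1]))
  if (is.na(n_hdr)) {
    stop("parse error at line 2: expected header/column counts, got: ",
         lines[2])
  }
  hdr <- lines[seq_len(n_hdr) + 2L]
  kv <- parse_atf_headers(hdr)
  data_lines <- lines[-seq_len(n_hdr + 3L)]  # skip column-title line
  mat <- parse_two_columns(data_lines, path)
  build_trace_from_columns(mat, kv)
}

parse_atf_headers <- function(hdr) {
  kv <- list()
  for (h in hdr) {
    h <- gsub("^\"|\"$", "", h)
    m <- regmatches(h, regexec("^([^=]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  out <- list(rate = NULL, voltage = NA_real_, t0 = 0, meta = list())
  num <- function(s) suppressWarnings(as.numeric(s))
  if (!is.null(kv[["SampleRate"]])) out$rate <- num(kv[["SampleRate"]])
  if (!is.null(kv[["HoldingVoltage"]])) {
    out$voltage <- num(kv[["HoldingVoltage"]])
  }
  if (!is.null(kv[["StartTime"]])) out$t0 <- num(kv[["StartTime"]])
  comments <- grep("^Comment ", names(kv), value = TRUE)
  for (k in comments) out$meta[[sub("^Comment ", "", k)]] <- kv[[k]]
  out
}

read_trace_tsv_file <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  kv <- list(rate = NULL, voltage = NA_real_, t0 = 0, meta = list())
  for (h in lines[hdr_idx]) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) != 3) stop("parse error in header line: ", h)
    key <- trimws(m[2]); val <- trimws(m[3])
    if (key == "rate") kv$rate <- suppressWarnings(as.numeric(val))
    else if (key == "voltage") kv$voltage <- suppressWarnings(as.numeric(val))
    else if (key == "t0") kv$t0 <- suppressWarnings(as.numeric(val))
    else if (startsWith(key, "meta.")) kv$meta[[sub("^meta\\.", "", key)]] <- val
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(body)]
  if (length(body) && grepl("^[A-Za-z]", body[1])) body <- body[-1]
  mat <- parse_two_columns(body, path)
  build_trace_from_columns(mat, kv)
}

parse_two_columns <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(matrix(numeric(0), ncol = 2))
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 2)[1]
  if (!is.na(bad)) {
    stop(sprintf("parse error in %s, data line %d: '%s'",
                 path, bad, lines[bad]))
  }
  cbind(as.numeric(vapply(parts, `[`, "", 1)),
        as.numeric(vapply(parts, `[`, "", 2)))
}

build_trace_from_columns <- function(mat, kv) {
  if (nrow(mat) == 0) {
    rate <- if (is.null(kv$rate)) 1000 else kv$rate
    return(current_trace(numeric(0), rate = rate, voltage = kv$voltage,
                         t0 = kv$t0, meta = kv$meta))
  }
  tt <- mat[, 1]
  if (nrow(mat) > 1) {
    steps <- diff(tt)
    if (any(steps <= 0) ||
        max(steps) - min(steps) > 1e-6 * stats::median(steps) + 1e-12) {
      stop("non-uniform time column: sampling must be uniform")
    }
  }
  rate <- kv$rate
  if (is.null(rate)) {
    if (nrow(mat) < 2) stop("cannot infer rate from a single sample")
    rate <- 1 / stats::median(diff(tt))
  }
  current_trace(mat[, 2], rate = rate, voltage = kv$voltage,
                t0 = tt[1], meta = kv$meta)
}

#' Write / read a detector event table
#'
#' Events are stored as TSV with columns `onset_s`, `end_s`,
#' `amplitude_pA`, `kind`.
#'
#' @param events Event data.frame from [detect_channel_events()].
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the data.frame.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset_s = events$onset_t, end_s = events$end_t,
                    amplitude_pA = events$amplitude, kind = events$kind)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read / write detector and controller configurations as JSON
#'
#' @param path File path.
#' @param cfg A `detector_config`, `contact_config`, or
#'   `controller_config`.
#' @return `read_config_json` returns the reconstructed config object
#'   (dispatched on the stored `type` field).
#' @export
write_config_json <- function(cfg, path) {
  type <- class(cfg)[1]
  jsonlite::write_json(c(list(type = type), unclass(cfg)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- x$type
  x$type <- NULL
  maker <- switch(type,
    detector_config = detector_config,
    contact_config = contact_config,
    controller_config = controller_config,
    abort_invalid(sprintf("unknown config type '%s'", type)))
  do.call(maker, x)
}

#' Generate the canonical test fixture set
#'
#' Writes, under `out_dir`, the deterministic fixtures the test suite and
#' examples use: the noiseless amplitude-by-duration pulse grid for the
#' detector rule oracle, short preset recordings over the I-V grid, a
#' forced three-channel superposition trace, and a rupture stream window,
#' together with `manifest.json` recording every ground-truth parameter.
#' Running twice with the same seed produces byte-identical files.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param amps Pulse-grid amplitudes, pA.
#' @param durs Pulse-grid durations, s.
#' @return The manifest, invisibly.
#' @export
generate_fixtures <- function(seed = 1, out_dir,
                              amps = c(1, 1.9, 2.1, 4, 5, 10),
                              durs = c(0.005, 0.02, 0.5, 0.99, 1.5)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, pulse_grid = list(), presets = list())

  # detector pulse grid: 4 s of flat baseline with one centered pulse,
  # 1 kHz, noiseless
  rate <- 1000
  for (a in amps) for (d in durs) {
    tr <- square_pulse_trace(a, d, rate = rate)
    nm <- sprintf("pulse_a%s_d%s.tsv", a, d)
    write_trace_tsv(tr, file.path(out_dir, nm))
    manifest$pulse_grid[[nm]] <- list(
      amplitude_pA = a, duration_s = d,
      is_channel_event = a > 2 && d >= 0.01 && d <= 1)
  }

  # short preset recordings across the I-V grid (2 s, single channel)
  for (p in scenario_preset()) {
    sc <- scenario_preset(p)
    for (v in c(-100, -60, 60, 100)) {
      tr <- render_trace(sc, voltage = v, duration = 2,
                         noise = noise_spec(), rate = 1000,
                         seed = derive_seed(seed, v + 1000), n_channels = 1)
      nm <- sprintf("%s_V%+d.tsv", p, v)
      write_trace_tsv(tr, file.path(out_dir, nm))
      manifest$presets[[nm]] <- list(
        scenario = p, voltage_mV = v,
        conductance_pS = sc$conductance_g,
        unitary_pA = sc$conductance_g * (v - sc$reversal_E) / 1000)
    }
  }

  # forced three-channel superposition (noiseless, fully open overlap)
  sc3 <- scenario_preset("kcsa_e71a_decane")
  tr3 <- render_trace(sc3, voltage = 100, duration = 5, noise = noise_off(),
                      rate = 1000, seed = derive_seed(seed, 33),
                      n_channels = 3)
  write_trace_tsv(tr3, file.path(out_dir, "three_channel.tsv"))
  manifest$three_channel <- list(
    n_channels = 3, unitary_pA = sc3$conductance_g * 0.1)

  # rupture window: sustained 500 pA
  rup <- current_trace(rep(500, 3 * 1000), rate = 1000, voltage = -60,
                       meta = list(kind = "rupture"))
  write_trace_tsv(rup, file.path(out_dir, "rupture_window.tsv"))
  manifest$rupture <- list(current_pA = 500, duration_s = 3)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Construct a noiseless square-pulse trace
#'
#' A flat zero trace with a single centered rectangular pulse; the basic
#' fixture for exercising the detection rule.
#'
#' @param amplitude Pulse amplitude, pA (signed).
#' @param duration Pulse duration, s.
#' @param total Total trace length, s. Default 4.
#' @param rate Sampling rate, Hz. Default 1000.
#' @param onset Pulse onset time, s. Default 1.
#' @return A `current_trace`.
#' @export
square_pulse_trace <- function(amplitude, duration, total = 4,
                               rate = 1000, onset = 1) {
  n <- round(total * rate)
  x <- numeric(n)
  i0 <- round(onset * rate) + 1L
  i1 <- min(n, i0 + round(duration * rate) - 1L)
  if (i1 >= i0) x[i0:i1] <- amplitude
  current_trace(x, rate = rate, voltage = NA_real_,
                meta = list(kind = "square_pulse"))
}
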