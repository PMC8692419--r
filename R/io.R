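# CSV dialect: comma-separated, `.` decimal, UTF-8, `#`-prefixed
# metadata/comment lines of the form `# key: value`. Traces are written
# at full double precision so a writer/reader round-trip is lossless.

parse_meta <- function(lines) {
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)\\s*$",
                           meta_lines))
  out <- list()
  for (m in kv) {
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      out[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  out
}

#' Read a time trace from CSV
#'
#' Expects a two-column numeric CSV (time in seconds, signal in a.u.)
#' with optional `# key: value` metadata header lines; recognized keys
#' `kind`, `wavelength_nm`, `irradiance_mW_cm2`, `duration_s` populate
#' the trace metadata.
#'
#' @param path Path to the CSV file.
#' @return A `kin_trace`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop_photokin("format", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta <- parse_meta(lines)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop_photokin("too_short", "fewer than 8 data rows in %s", path)
  d <- tryCatch(utils::read.csv(text = paste(body, collapse = "\n")),
                error = function(e) stop_photokin("format", "cannot parse %s: %s",
                                                  path, conditionMessage(e)))
  if (ncol(d) < 2 || !all(vapply(d[1:2], is.numeric, logical(1)))) {
    stop_photokin("format", "%s must have two numeric columns (time, signal)", path)
  }
  if (nrow(d) < 8) stop_photokin("too_short", "fewer than 8 data rows in %s", path)
  if (any(diff(d[[1]]) <= 0)) {
    stop_photokin("format", "time column in %s is not strictly increasing", path)
  }
  kind <- meta$kind %||% "switch_on_off"
  if (!kind %in% c("photoconversion", "switch_on_off", "relaxation")) {
    kind <- "switch_on_off"
  }
  illum <- meta[setdiff(names(meta), "kind")]
  time_trace(d[[1]], d[[2]], kind = kind, illumination = illum)
}

#' Write a time trace to CSV
#'
#' Writes metadata as `# key: value` header lines followed by `t,y` data
#' at full double precision (lossless round-trip through
#' [read_trace_csv()]).
#'
#' @param trace A `kin_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  tr <- as_time_trace(trace)
  meta <- c(list(kind = attr(tr, "kind")), attr(tr, "illumination"))
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) format(v, digits = 17), character(1)))
  rows <- sprintf("%.17g,%.17g", tr$t, tr$y)
  writeLines(c(hdr, "t,y", rows), path)
  invisible(path)
}

#' Write a cycle series as per-cycle CSVs plus a JSON manifest
#'
#' @param series A [cycle_series()].
#' @param dir Output directory (created if missing).
#' @param seed Optional integer recorded in the manifest for provenance.
#' @return The manifest path, invisibly.
#' @export
write_cycle_series <- function(series, dir, seed = NULL) {
  stopifnot(inherits(series, "cycle_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("cycle_%02d.csv", seq_along(series$cycles))
  for (i in seq_along(series$cycles)) {
    write_trace_csv(series$cycles[[i]], file.path(dir, files[i]))
  }
  manifest <- list(cycles = files, buffer_ph = series$buffer_ph,
                   regeneration = series$regeneration)
  if (!is.null(seed)) manifest$seed <- seed
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read a cycle series from a manifest directory
#'
#' @param dir Directory containing `manifest.json` (keys `cycles`,
#'   `buffer_ph`, `regeneration`) and the per-cycle CSVs it references.
#' @return A [cycle_series()].
#' @export
read_cycle_series <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_photokin("format", "no manifest.json in %s", dir)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cycles <- lapply(file.path(dir, m$cycles), read_trace_csv)
  cycle_series(cycles,
               buffer_ph = m$buffer_ph %||% 9.2,
               regeneration = as.list(m$regeneration %||% list()))
}

#' Assemble a kinetic-parameter report table
#'
#' One row per variant in the layout of the standard kinetics table:
#' first- and second-cycle switching parameters (amplitude ratio and
#' rates with standard errors), off-to-on recovery rate, and
#' photoconversion rates, all rates in 1e-3 s^-1. Metrics that are
#' missing (non-convergent fits, absent components such as the second
#' exponential of mono-exponential C175A-type cycles) become empty cells.
#'
#' @param results A list of entries, each a list with elements `variant`
#'   (character), and optionally `cycles` (a `cycle_metrics`), `recovery`
#'   (a relaxation `kin_fit`) and `conversion` (a photoconversion
#'   `kin_fit`).
#' @return A tibble, one row per entry, in input order.
#' @export
report_table <- function(results) {
  if (!length(results)) stop_photokin("invalid_parameter", "need >= 1 result")
  e3 <- function(x) if (is.null(x) || !length(x) || !is.finite(x)) NA_real_ else x * 1e3
  num <- function(x) if (is.null(x) || !length(x) || !is.finite(x)) NA_real_ else x
  row_of <- function(res) {
    pc <- if (!is.null(res$cycles)) res$cycles$per_cycle else NULL
    cyc <- function(i, col) if (!is.null(pc) && nrow(pc) >= i) pc[[col]][i] else NA_real_
    conv <- res$conversion; rec <- res$recovery
    tibble::tibble(
      variant = res$variant,
      sw1_i2_i1 = num(cyc(1, "i2_i1")),
      sw1_k1_1e3 = e3(cyc(1, "k1")), sw1_k1_se_1e3 = e3(cyc(1, "k1_se")),
      sw1_k2_1e3 = e3(cyc(1, "k2")), sw1_k2_se_1e3 = e3(cyc(1, "k2_se")),
      sw2_i2_i1 = num(cyc(2, "i2_i1")),
      sw2_k1_1e3 = e3(cyc(2, "k1")), sw2_k1_se_1e3 = e3(cyc(2, "k1_se")),
      sw2_k2_1e3 = e3(cyc(2, "k2")), sw2_k2_se_1e3 = e3(cyc(2, "k2_se")),
      recovery_k_1e3 = e3(if (!is.null(rec)) rec$params[["k"]]),
      recovery_k_se_1e3 = e3(if (!is.null(rec)) rec$stderr[["k"]]),
      conv_k1_1e3 = e3(if (!is.null(conv)) conv$params[["k1"]]),
      conv_k1_se_1e3 = e3(if (!is.null(conv)) conv$stderr[["k1"]]),
      conv_k2_1e3 = e3(if (!is.null(conv)) conv$params[["k2"]]),
      conv_k2_se_1e3 = e3(if (!is.null(conv)) conv$stderr[["k2"]])
    )
  }
  dplyr::bind_rows(lapply(results, row_of))
}

#' Write the report table to CSV
#'
#' @inheritParams report_table
#' @param path Output CSV path; missing metrics are written as empty
#'   cells.
#' @return The table, invisibly.
#' @export
write_report <- function(results, path) {
  tab <- report_table(results)
  readr::write_csv(tab, path, na = "")
  invisible(tab)
}
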