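# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# r^2 of a fitted lm without summary.lm's perfect-fit warning; an exact
# fit (or zero-variance response) reports 1.
lm_r_squared <- function(fit) {
  y <- stats::fitted(fit) + stats::resid(fit)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - sum(stats::resid(fit)^2) / tss))
}

#' Derive a reproducible sub-seed from a base seed and a counter
#'
#' All simulator sub-draws derive their RNG state from `(seed, index)` so
#' that adding one more curve or group to a scenario never shifts the noise
#' of the others. Kept below 2^31 - 1 so the result is a valid R seed.
#'
#' @param seed base integer seed.
#' @param index non-negative integer counter.
#' @return an integer seed.
#' @keywords internal
sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + as.double(index) * 7919) %% 2147483647)
}

# Flat "key: value" config reader ("key = value" also accepted). Blank lines
# and lines starting with '#' are ignored. Values that parse as numbers are
# returned numeric; comma-separated values become vectors.
read_kv_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=]+)[:=](.*)$", ln))[[1]]
    if (length(m) != 3L) stop_input("malformed config line: '%s'", ln)
    key <- trimws(m[2])
    val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (length(parts) > 0 && !anyNA(nums)) nums else val
  }
  out
}

# Sniff the delimiter of a delimited text file from its header line.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop_input("empty file: %s", path)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  utils::read.delim(path, sep = sniff_delim(path), stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Unit conversion factors to canonical units (seconds, micromolar).
time_factor <- function(unit) {
  switch(unit,
         s = 1, sec = 1, seconds = 1,
         min = 60, minutes = 60,
         h = 3600, hr = 3600, hours = 3600,
         stop_input("unknown time unit: '%s'", unit))
}

conc_factor <- function(unit) {
  switch(unit,
         uM = 1, um = 1, micromolar = 1,
         nM = 1e-3, nm = 1e-3,
         mM = 1e3,
         M = 1e6,
         stop_input("unknown concentration unit: '%s'", unit))
}
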