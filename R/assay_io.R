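# Domain containers and readers for the assay tables and sequence files
# consumed by the pipeline. Canonical units throughout: seconds for kinetic
# time, minutes for stability time courses, micromolar for concentrations.

#' Progress curve: one timed product-accumulation trace
#'
#' Container for a single plate-reader progress curve together with the
#' enzyme, inhibitor and reporter-substrate concentrations under which it
#' was recorded. Times are in seconds, concentrations in micromolar.
#'
#' @param curve_id character identifier for the curve.
#' @param times numeric vector of times (s), strictly increasing, length >= 5
#'   for fitting (shorter curves may be constructed but not fitted).
#' @param signal numeric product signal, same length as `times`. Absorbance
#'   units, fluorescence units, or a product concentration, per `signal_kind`.
#' @param inhibitor_conc,enzyme_conc,substrate_conc scalar concentrations
#'   (uM), all non-negative.
#' @param signal_kind one of `"absorbance"`, `"fluorescence"`,
#'   `"concentration"`. Records (rather than resolves) whether the 405 nm
#'   readout was converted to product concentration.
#' @return an object of class `progress_curve`.
#' @examples
#' pc <- progress_curve("c1", times = seq(0, 120, 30),
#'                      signal = c(0, 0.02, 0.035, 0.045, 0.05),
#'                      inhibitor_conc = 1, enzyme_conc = 0.2,
#'                      substrate_conc = 200)
#' @export
progress_curve <- function(curve_id, times, signal, inhibitor_conc,
                           enzyme_conc, substrate_conc,
                           signal_kind = c("absorbance", "fluorescence",
                                           "concentration")) {
  signal_kind <- match.arg(signal_kind)
  stopifnot(is.character(curve_id), length(curve_id) == 1L)
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal))
    stop_input("curve '%s': times and signal lengths differ", curve_id)
  if (any(!is.finite(times)) || any(!is.finite(signal)))
    stop_input("curve '%s': non-finite times or signal", curve_id)
  if (any(diff(times) <= 0))
    stop_input("curve '%s': times must be strictly increasing", curve_id)
  for (nm in c("inhibitor_conc", "enzyme_conc", "substrate_conc")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0)
      stop_input("curve '%s': %s must be a non-negative number", curve_id, nm)
  }
  structure(
    list(curve_id = curve_id, times = times, signal = signal,
         inhibitor_conc = inhibitor_conc, enzyme_conc = enzyme_conc,
         substrate_conc = substrate_conc, signal_kind = signal_kind),
    class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf(
    "<progress_curve '%s': %d points, t = %g..%g s, [I] = %g uM, [E] = %g uM, [S] = %g uM>\n",
    x$curve_id, length(x$times), min(x$times), max(x$times),
    x$inhibitor_conc, x$enzyme_conc, x$substrate_conc))
  invisible(x)
}

#' Stoichiometry-of-inhibition titration series
#'
#' Fractional protease activity as a function of the inhibitor:enzyme molar
#' ratio \[I0\]/\[E0\].
#'
#' @param protease_id character label of the target protease.
#' @param ratio numeric non-negative inhibitor:enzyme ratios.
#' @param fractional_activity numeric activities, nominally in \[0, 1\]
#'   (small noise overshoot above 1 is tolerated).
#' @param enzyme_conc scalar enzyme concentration (uM).
#' @return an object of class `titration_series`.
#' @export
titration_series <- function(protease_id, ratio, fractional_activity,
                             enzyme_conc = NA_real_) {
  ratio <- as.numeric(ratio)
  fractional_activity <- as.numeric(fractional_activity)
  if (length(ratio) != length(fractional_activity))
    stop_input("titration: ratio and fractional_activity lengths differ")
  if (any(ratio < 0)) stop_input("titration: ratios must be non-negative")
  if (any(!is.finite(fractional_activity)))
    stop_input("titration: non-finite fractional activity")
  if (any(ratio == 0) && abs(mean(fractional_activity[ratio == 0]) - 1) > 0.2)
    warning("fractional activity at ratio 0 is far from 1", call. = FALSE)
  o <- order(ratio)
  structure(
    list(protease_id = protease_id, ratio = ratio[o],
         fractional_activity = fractional_activity[o],
         enzyme_conc = enzyme_conc),
    class = "titration_series")
}

#' Inactivation decay series for one stress condition
#'
#' Residual inhibitory activity (percent of the t = 0 activity) over
#' incubation time at one temperature or pH. Times are in minutes; hours
#' are accepted through the reader's unit declaration and converted.
#'
#' @param condition_kind `"temperature"` or `"pH"`.
#' @param condition_value the condition (degrees C or pH units).
#' @param times numeric non-negative times (min).
#' @param residual_activity percent of initial activity; the t = 0 value
#'   should be 100 within noise.
#' @return an object of class `decay_series`.
#' @export
decay_series <- function(condition_kind = c("temperature", "pH"),
                         condition_value, times, residual_activity) {
  condition_kind <- match.arg(condition_kind)
  times <- as.numeric(times)
  residual_activity <- as.numeric(residual_activity)
  if (length(times) != length(residual_activity))
    stop_input("decay: times and residual_activity lengths differ")
  if (any(times < 0)) stop_input("decay: times must be non-negative")
  o <- order(times)
  times <- times[o]; residual_activity <- residual_activity[o]
  if (any(times == 0)) {
    a0 <- residual_activity[times == 0][1]
    if (abs(a0 - 100) > 25)
      warning(sprintf("t = 0 residual activity is %g%%, expected ~100%%", a0),
              call. = FALSE)
  }
  structure(
    list(condition_kind = condition_kind, condition_value = condition_value,
         times = times, residual_activity = residual_activity),
    class = "decay_series")
}

#' Single activity measurement in a grouped assay
#'
#' One replicate of a protease-activity assay (e.g. fecal protease activity
#' on casein), used by [summarize_groups()]. A set of measurements is a
#' plain data frame with columns `group_label`, `replicate_id`, `activity`.
#'
#' @param group_label character group name (e.g. "PBS", "DSS").
#' @param replicate_id character replicate identifier.
#' @param activity non-negative signal rate.
#' @return a one-row data.frame.
#' @export
activity_measurement <- function(group_label, replicate_id, activity) {
  if (!is_scalar_number(activity) || activity < 0)
    stop_input("activity must be a non-negative number")
  data.frame(group_label = group_label, replicate_id = replicate_id,
             activity = activity, stringsAsFactors = FALSE)
}

#' Annotated serpin sequence record
#'
#' Amino-acid sequence with optional structural annotation: signal-peptide
#' span, reactive-center-loop (RCL) span, P1 residue index and an assigned
#' scissile bond. All coordinates are 1-based inclusive, in the
#' "Val338-Met339" style.
#'
#' @param seq_id character identifier.
#' @param residues amino-acid string over the 20-letter alphabet.
#' @param signal_peptide_span,rcl_span optional length-2 integer vectors
#'   `c(start, end)`, 1-based inclusive.
#' @param p1_index optional 1-based index of the P1 residue; must lie within
#'   `rcl_span` when both are set.
#' @param cleavage_bond optional length-2 vector `c(i, i + 1)` of consecutive
#'   residue indices flanking the scissile bond.
#' @return an object of class `serpin_record`.
#' @examples
#' serpin_record("s1", "MKVLAAGGSTTAVM", rcl_span = c(6, 14), p1_index = 13)
#' @export
serpin_record <- function(seq_id, residues, signal_peptide_span = NULL,
                          rcl_span = NULL, p1_index = NULL,
                          cleavage_bond = NULL) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- validate_aa(residues)
  if (length(bad))
    stop_input("sequence '%s' contains non-amino-acid characters: %s",
               seq_id, paste(unique(bad), collapse = ", "))
  n <- nchar(residues)
  check_span <- function(span, what) {
    if (is.null(span)) return(NULL)
    span <- as.integer(span)
    if (length(span) != 2L || any(span < 1L) || span[2] > n || span[1] > span[2])
      stop_input("'%s': invalid %s for a %d-residue sequence", seq_id, what, n)
    span
  }
  signal_peptide_span <- check_span(signal_peptide_span, "signal_peptide_span")
  rcl_span <- check_span(rcl_span, "rcl_span")
  if (!is.null(p1_index)) {
    p1_index <- as.integer(p1_index)
    if (p1_index < 1L || p1_index > n)
      stop_input("'%s': p1_index outside sequence", seq_id)
    if (!is.null(rcl_span) &&
        (p1_index < rcl_span[1] || p1_index > rcl_span[2]))
      stop_input("'%s': p1_index must lie within rcl_span", seq_id)
  }
  if (!is.null(cleavage_bond)) {
    cleavage_bond <- as.integer(cleavage_bond)
    if (length(cleavage_bond) != 2L || cleavage_bond[2] != cleavage_bond[1] + 1L ||
        cleavage_bond[1] < 1L || cleavage_bond[2] > n)
      stop_input("'%s': cleavage_bond must be consecutive indices (i, i+1) within the sequence",
                 seq_id)
  }
  structure(
    list(seq_id = seq_id, residues = residues,
         signal_peptide_span = signal_peptide_span, rcl_span = rcl_span,
         p1_index = p1_index, cleavage_bond = cleavage_bond),
    class = "serpin_record")
}

#' @export
print.serpin_record <- function(x, ...) {
  cat(sprintf("<serpin_record '%s': %d aa%s%s>\n", x$seq_id,
              nchar(x$residues),
              if (!is.null(x$rcl_span))
                sprintf(", RCL %d-%d", x$rcl_span[1], x$rcl_span[2]) else "",
              if (!is.null(x$p1_index))
                sprintf(", P1 = %d", x$p1_index) else ""))
  invisible(x)
}

# Returns the offending characters (empty if the string is a valid
# 20-letter amino-acid sequence).
validate_aa <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  chars[!chars %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]
}

#' Read a progress-curve table
#'
#' Reads a delimited text table (comma or tab, auto-detected from the
#' header) with one row per time point and groups rows into
#' [progress_curve()] objects. The `schema` argument remaps column names
#' and declares input units, which are converted to the canonical
#' seconds / micromolar.
#'
#' @param path path to the table.
#' @param schema optional list with elements `columns` (named character
#'   vector mapping canonical names `curve_id`, `time`, `signal`,
#'   `inhibitor`, `enzyme`, `substrate` to file column names), `time_unit`
#'   (`"s"`, `"min"`, `"h"`), `conc_unit` (`"uM"`, `"nM"`, `"mM"`, `"M"`)
#'   and `signal_kind`. Defaults match the columns
#'   `curve_id, time_s, signal, inhibitor_uM, enzyme_uM, substrate_uM`.
#' @return a list of `progress_curve` objects, one per `curve_id`, rows
#'   sorted by time.
#' @export
read_progress_table <- function(path, schema = NULL) {
  cols <- c(curve_id = "curve_id", time = "time_s", signal = "signal",
            inhibitor = "inhibitor_uM", enzyme = "enzyme_uM",
            substrate = "substrate_uM")
  tu <- "s"; cu <- "uM"; sk <- "absorbance"
  if (!is.null(schema)) {
    if (!is.null(schema$columns)) cols[names(schema$columns)] <- schema$columns
    tu <- schema$time_unit %||% tu
    cu <- schema$conc_unit %||% cu
    sk <- schema$signal_kind %||% sk
  }
  df <- read_delim_auto(path)
  missing <- cols[!cols %in% names(df)]
  if (length(missing))
    stop_input("missing column(s) in %s: %s", path,
               paste(missing, collapse = ", "))
  tf <- time_factor(tu); cf <- conc_factor(cu)
  for (nm in cols[c("inhibitor", "enzyme", "substrate")]) {
    neg <- which(df[[nm]] < 0)
    if (length(neg))
      stop_input("negative concentration in column '%s' at row %d", nm, neg[1])
  }
  ids <- unique(df[[cols["curve_id"]]])
  lapply(ids, function(id) {
    rows <- df[df[[cols["curve_id"]]] == id, , drop = FALSE]
    rows <- rows[order(rows[[cols["time"]]]), , drop = FALSE]
    if (anyDuplicated(rows[[cols["time"]]]))
      stop_input("curve '%s': duplicated time points", id)
    progress_curve(
      curve_id = as.character(id),
      times = rows[[cols["time"]]] * tf,
      signal = rows[[cols["signal"]]],
      inhibitor_conc = rows[[cols["inhibitor"]]][1] * cf,
      enzyme_conc = rows[[cols["enzyme"]]][1] * cf,
      substrate_conc = rows[[cols["substrate"]]][1] * cf,
      signal_kind = sk)
  })
}

#' Read a titration table
#'
#' Expects columns `protease_id, ratio, fractional_activity` (plus optional
#' `enzyme_uM`); returns one [titration_series()] per protease.
#'
#' @param path path to a delimited text table.
#' @return a list of `titration_series`.
#' @export
read_titration_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("protease_id", "ratio", "fractional_activity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_input("missing column(s) in %s: %s", path,
               paste(missing, collapse = ", "))
  neg <- which(df$ratio < 0)
  if (length(neg))
    stop_input("negative ratio at row %d", neg[1])
  lapply(unique(df$protease_id), function(id) {
    rows <- df[df$protease_id == id, , drop = FALSE]
    titration_series(as.character(id), rows$ratio, rows$fractional_activity,
                     enzyme_conc = (rows$enzyme_uM %||% NA_real_)[1])
  })
}

#' Read a stability (decay) table
#'
#' Expects columns `condition_kind, condition_value, time_min, residual_pct`
#' (`time_h` accepted instead of `time_min`, converted to minutes); returns
#' one [decay_series()] per condition.
#'
#' @param path path to a delimited text table.
#' @return a list of `decay_series`.
#' @export
read_decay_table <- function(path) {
  df <- read_delim_auto(path)
  tcol <- intersect(c("time_min", "time_h"), names(df))
  need <- c("condition_kind", "condition_value", "residual_pct")
  missing <- setdiff(need, names(df))
  if (length(missing) || length(tcol) == 0L)
    stop_input("missing column(s) in %s: %s", path,
               paste(c(missing, if (!length(tcol)) "time_min"), collapse = ", "))
  tcol <- tcol[1]
  tf <- if (tcol == "time_h") 60 else 1
  key <- paste(df$condition_kind, df$condition_value)
  lapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    decay_series(rows$condition_kind[1], rows$condition_value[1],
                 rows[[tcol]] * tf, rows$residual_pct)
  })
}

#' Read grouped activity measurements
#'
#' Expects columns `group_label, replicate_id, activity`.
#'
#' @param path path to a delimited text table.
#' @return a data.frame of measurements.
#' @export
read_activity_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("group_label", "replicate_id", "activity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_input("missing column(s) in %s: %s", path,
               paste(missing, collapse = ", "))
  neg <- which(df$activity < 0)
  if (length(neg)) stop_input("negative activity at row %d", neg[1])
  df[, need]
}

#' Read and write amino-acid FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O that validate the 20-letter
#' amino-acid alphabet and return [serpin_record()] objects. Writing then
#' reading reproduces ids and residues exactly.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: a list of `serpin_record`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i) {
    id <- strsplit(names(set)[i], "[ \t]")[[1]][1]
    serpin_record(id, as.character(set[[i]]))
  })
}

#' @rdname read_fasta
#' @param records a list of `serpin_record` (or a single record).
#' @return `write_fasta`: the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "serpin_record")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- vapply(records, `[[`, "", "seq_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
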