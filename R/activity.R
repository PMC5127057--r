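# Protease-panel and fecal-protease inhibition summaries: percent residual
# activity relative to an uninhibited control, fold changes between
# treatment groups, and per-group mean +/- SEM tables. Significance testing
# (Kruskal-Wallis / Dunn) is deliberately left to standard routines; this
# module emits the table those tests consume.

#' Percent residual (and percent inhibition) of a protease activity
#'
#' Activities measured without inhibitor define 100 percent. Both residual
#' and inhibition percentages are returned, since "reduced to 50%" and
#' "decreased by 30%" phrasings coexist in assay reports.
#'
#' @param with_inhibitor rate measured in the presence of the inhibitor.
#' @param control rate of the uninhibited control (> 0).
#' @return list with `residual_pct` (100 x with/control) and
#'   `inhibition_pct` (100 - residual).
#' @examples
#' percent_residual(0.7, 1.0)  # 70% residual = 30% inhibition
#' @export
percent_residual <- function(with_inhibitor, control) {
  if (any(control <= 0)) stop_input("control rate must be > 0")
  residual <- 100 * with_inhibitor / control
  list(residual_pct = residual, inhibition_pct = 100 - residual)
}

#' Fold change between two group means
#'
#' @param treated,control either `group_summary` rows (as returned by
#'   [summarize_groups()]) or bare numeric means.
#' @return `treated mean / control mean`.
#' @export
fold_change <- function(treated, control) {
  get_mean <- function(x) {
    if (is.data.frame(x)) x$mean_activity[1]
    else if (is.list(x)) x$mean_activity
    else as.numeric(x)
  }
  m_t <- get_mean(treated); m_c <- get_mean(control)
  if (!is_scalar_number(m_c) || m_c <= 0)
    stop_input("control mean must be > 0")
  m_t / m_c
}

#' Per-group mean and SEM of activity measurements
#'
#' @param measurements data.frame with columns `group_label`,
#'   `replicate_id`, `activity` (see [activity_measurement()] /
#'   [read_activity_table()]).
#' @return data.frame of class `group_summary` with one row per group:
#'   `group_label`, `n`, `mean_activity`, `sem` (sample sd / sqrt(n)).
#'   Single-replicate groups get `sem = 0` with a warning.
#' @export
summarize_groups <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  need <- c("group_label", "activity")
  missing <- setdiff(need, names(measurements))
  if (length(missing))
    stop_input("missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(measurements) == 0L) stop_input("no measurements")
  groups <- unique(measurements$group_label)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- measurements$activity[measurements$group_label == g]
    n <- length(x)
    sem <- if (n == 1L) {
      warning(sprintf("group '%s' has a single replicate; SEM set to 0", g),
              call. = FALSE)
      0
    } else stats::sd(x) / sqrt(n)
    data.frame(group_label = g, n = n, mean_activity = mean(x), sem = sem,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("group_summary", class(out))
  out
}
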