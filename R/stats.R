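#' Median and range summary
#'
#' Cohort cells are reported as median (min--max): the middle order statistic
#' (mean of the two middle values for even n) with the exact extremes.
#'
#' @param x non-empty numeric vector.
#' @return named numeric vector `c(median, min, max)`.
#' @export
median_min_max <- function(x) {
  if (length(x) == 0L) stop("empty input")
  c(median = stats::median(x), min = min(x), max = max(x))
}

#' Percent change from baseline
#'
#' `100 * (value - baseline) / baseline`, the per-subject
#' \eqn{\Delta RMS_{oxy}} convention (and any other percent-change metric).
#'
#' @param baseline non-zero baseline value.
#' @param value value to compare.
#' @return percent change (vectorised over `value` / `baseline`).
#' @export
percent_change <- function(baseline, value) {
  if (any(baseline == 0)) stop("zero baseline")
  100 * (value - baseline) / baseline
}

# Exact null distribution of the positive-rank sum by dynamic programming.
# `ranks2` are doubled (mid-)ranks, so they are integers even with ties.
# Returns counts over achievable doubled sums 0..sum(ranks2); total 2^m.
.signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Tests paired measurements `condition` versus `baseline` with the Wilcoxon
#' signed-rank statistic \eqn{W} = sum of the ranks of the positive
#' differences (mid-ranks for tied magnitudes).  For up to `exact_max` usable
#' pairs the p-value is exact: the full null distribution over all \eqn{2^m}
#' sign assignments is built by dynamic programming on doubled ranks (kept
#' integral even with mid-ranks).  Above `exact_max` a normal approximation
#' with continuity correction and tie-corrected variance is used.
#'
#' Zero differences are handled by `zero_policy`:
#' \describe{
#'   \item{`drop` (default)}{zeros removed before ranking (classical
#'     Wilcoxon); if every difference is zero the test is degenerate and
#'     returns `W = 0`, `p = 1`.}
#'   \item{`pratt`}{zeros included when ranking magnitudes, then their ranks
#'     discarded from the statistic and from the sign enumeration.}
#' }
#'
#' @param baseline,condition equal-length numeric vectors of paired values.
#' @param zero_policy `"drop"` or `"pratt"`.
#' @param alternative `"two_sided"` (default, `min(1, 2 x smaller tail)`),
#'   `"greater"` (condition > baseline) or `"less"`.
#' @param exact_max largest number of non-zero pairs for which the exact
#'   enumeration is used (default 25).
#' @return list with `statistic` (W), `p_value`, `n` (input pairs), `m`
#'   (pairs entering the statistic), `method`, `alternative`, `zero_policy`.
#' @examples
#' # 7 all-positive differences with distinct magnitudes: smallest
#' # attainable two-sided p, 2 / 2^7
#' wilcoxon_exact(rep(0, 7), 1:7)$p_value  # 0.015625
#' @export
wilcoxon_exact <- function(baseline, condition,
                           zero_policy = c("drop", "pratt"),
                           alternative = c("two_sided", "greater", "less"),
                           exact_max = 25L) {
  zero_policy <- match.arg(zero_policy)
  alternative <- match.arg(alternative)
  if (length(baseline) != length(condition))
    stop("baseline and condition must have equal length")
  n <- length(baseline)
  if (n < 1L) stop("need at least one pair")
  d <- condition - baseline
  if (zero_policy == "drop") {
    d <- d[d != 0]
    if (length(d) == 0L)
      return(list(statistic = 0, p_value = 1, n = n, m = 0L,
                  method = "degenerate (all differences zero)",
                  alternative = alternative, zero_policy = zero_policy))
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    active <- r
  } else {
    r <- rank(abs(d))            # zeros participate in the ranking ...
    W <- sum(r[d > 0])
    active <- r[d != 0]          # ... but not in the statistic or the null
    if (length(active) == 0L)
      return(list(statistic = 0, p_value = 1, n = n, m = 0L,
                  method = "degenerate (all differences zero)",
                  alternative = alternative, zero_policy = zero_policy))
  }
  m <- length(active)
  if (m <= exact_max) {
    r2 <- as.integer(round(2 * active))
    counts <- .signed_rank_counts(r2)
    total <- 2^m
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / total
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    method <- "exact (signed-rank enumeration)"
  } else {
    mu <- sum(active) / 2
    sd0 <- sqrt(sum(active^2) / 4)
    p_ge <- stats::pnorm((W - mu - 0.5) / sd0, lower.tail = FALSE)
    p_le <- stats::pnorm((W - mu + 0.5) / sd0)
    method <- "normal approximation with continuity correction"
  }
  p <- switch(alternative,
              two_sided = min(1, 2 * min(p_ge, p_le)),
              greater = p_ge,
              less = p_le)
  list(statistic = W, p_value = p, n = n, m = m, method = method,
       alternative = alternative, zero_policy = zero_policy)
}

#' Summarize a cohort metric table into a report grid
#'
#' Builds the cohort report: one cell per metric x phase holding the
#' median (min--max) across subjects, plus an exact Wilcoxon signed-rank
#' p-value of that phase against the designated baseline phase (paired within
#' subject; subjects missing at either side of a pair are dropped and `n`
#' reflects the pairs used).  Metrics listed in `pct_change_of` are derived
#' per subject via [percent_change()] against the baseline phase and then
#' summarized the same way, with their p-value from a one-sample signed-rank
#' test of the percent changes against zero.
#'
#' @param metrics data.frame with columns `subject`, `metric`, `phase`,
#'   `value` (one value per subject x metric x phase).
#' @param baseline label of the baseline phase (default `"baseline"`).
#' @param phases phase labels and their order in the report; default: order
#'   of appearance in `metrics`.
#' @param pct_change_of named character vector mapping derived-metric names
#'   to source metrics, e.g. `c(drms_oxy_pct = "rms_oxy")`.
#' @param alpha significance level for the `significant` flag (default 0.05,
#'   flagged at `p <= alpha`).
#' @param ... passed to [wilcoxon_exact()] (e.g. `zero_policy`).
#' @return A `cohort_summary`: data.frame with columns `metric`, `phase`,
#'   `n`, `median`, `min`, `max`, `p`, `significant`.  `p` is `NA` for the
#'   baseline column and for cells with fewer than 2 pairs; it is stored
#'   unrounded (the printed report rounds to 2 decimals).
#' @export
summarize_cohort <- function(metrics, baseline = "baseline", phases = NULL,
                             pct_change_of = c(drms_oxy_pct = "rms_oxy"),
                             alpha = 0.05, ...) {
  need <- c("subject", "metric", "phase", "value")
  if (!all(need %in% names(metrics)))
    stop("metrics needs columns ", paste(need, collapse = ", "))
  metrics <- as.data.frame(metrics)[, need]
  if (is.null(phases)) phases <- unique(as.character(metrics$phase))
  if (!baseline %in% phases) stop("baseline phase '", baseline, "' not present")
  metric_names <- unique(as.character(metrics$metric))

  # derive percent-change metrics per subject against the baseline phase
  for (dm in names(pct_change_of)) {
    src <- pct_change_of[[dm]]
    if (!src %in% metric_names) next
    sub <- metrics[metrics$metric == src, ]
    base <- sub[sub$phase == baseline, c("subject", "value")]
    names(base)[2] <- "base_value"
    oth <- merge(sub[sub$phase != baseline, ], base, by = "subject")
    if (nrow(oth) == 0L) next
    metrics <- rbind(metrics,
                     data.frame(subject = oth$subject, metric = dm,
                                phase = oth$phase,
                                value = percent_change(oth$base_value,
                                                       oth$value)))
    metric_names <- c(metric_names, dm)
  }

  rows <- list()
  for (mn in metric_names) {
    sub <- metrics[metrics$metric == mn, ]
    derived <- mn %in% names(pct_change_of)
    base <- sub[sub$phase == baseline, c("subject", "value")]
    for (ph in phases) {
      cell <- sub[sub$phase == ph, ]
      if (nrow(cell) == 0L) next
      mmm <- median_min_max(cell$value)
      p <- NA_real_
      n_used <- nrow(cell)
      if (ph != baseline) {
        if (derived) {
          if (nrow(cell) >= 2L)
            p <- wilcoxon_exact(rep(0, nrow(cell)), cell$value, ...)$p_value
        } else {
          pr <- merge(base, cell[, c("subject", "value")], by = "subject",
                      suffixes = c("_base", "_cond"))
          n_used <- nrow(pr)
          if (n_used >= 2L)
            p <- wilcoxon_exact(pr$value_base, pr$value_cond, ...)$p_value
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(metric = mn, phase = ph, n = n_used,
                   median = unname(mmm["median"]), min = unname(mmm["min"]),
                   max = unname(mmm["max"]), p = p,
                   significant = !is.na(p) & p <= alpha)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "phases") <- phases
  attr(out, "alpha") <- alpha
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Format a cohort summary as an aligned text table
#'
#' One row per metric, one column block per phase showing
#' `median (min--max)` to 3 significant figures, with the Wilcoxon p rounded
#' to two decimals and starred when significant.
#'
#' @param x a `cohort_summary`.
#' @return character vector of lines.
#' @export
format_cohort_summary <- function(x) {
  stopifnot(inherits(x, "cohort_summary"))
  phases <- attr(x, "phases")
  fmt_cell <- function(row) {
    if (nrow(row) == 0L) return("")
    s <- sprintf("%s (%s - %s)", signif(row$median, 3), signif(row$min, 3),
                 signif(row$max, 3))
    if (!is.na(row$p))
      s <- sprintf("%s  p=%.2f%s", s, row$p, if (row$significant) "*" else " ")
    s
  }
  metrics <- unique(x$metric)
  grid <- matrix("", nrow = length(metrics), ncol = length(phases),
                 dimnames = list(metrics, phases))
  for (i in seq_along(metrics)) for (j in seq_along(phases))
    grid[i, j] <- fmt_cell(x[x$metric == metrics[i] & x$phase == phases[j], ])
  widths <- pmax(nchar(phases), apply(nchar(grid), 2, max))
  mw <- max(nchar(metrics), nchar("metric"))
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  header <- paste(c(pad("metric", mw),
                    mapply(pad, phases, widths)), collapse = "  ")
  lines <- c(header, strrep("-", nchar(header)))
  for (i in seq_along(metrics))
    lines <- c(lines, paste(c(pad(metrics[i], mw),
                              mapply(pad, grid[i, ], widths)), collapse = "  "))
  c(lines, "", sprintf("Data as median (min - max); * p <= %.2f (exact Wilcoxon signed-rank vs '%s').",
                       attr(x, "alpha"), attr(x, "baseline")))
}

#' @export
print.cohort_summary <- function(x, ...) {
  writeLines(format_cohort_summary(x))
  invisible(x)
}

#' Write a cohort summary (tidy CSV and aligned text)
#'
#' @param x a `cohort_summary`.
#' @param csv_path tidy CSV destination (unrounded values), or `NULL` to skip.
#' @param txt_path aligned-text destination, or `NULL` to skip.
#' @export
write_cohort_summary <- function(x, csv_path = NULL, txt_path = NULL) {
  stopifnot(inherits(x, "cohort_summary"))
  if (!is.null(csv_path))
    data.table::fwrite(data.table::as.data.table(as.data.frame(x)),
                       csv_path, sep = ",", dec = ".")
  if (!is.null(txt_path)) writeLines(format_cohort_summary(x), txt_path)
  invisible(x)
}
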