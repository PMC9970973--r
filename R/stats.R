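#' Build a 2x2 contingency table from cell records
#'
#' Rows are the two groups (in the declared order of `group_levels`),
#' columns are outcome yes/no.
#'
#' @param records Data frame of per-FOV records (e.g. from
#'   [classify_cohort()] or [cohort_truth_records()]).
#' @param group_by Name of a column with exactly two distinct values.
#' @param outcome Name of a logical column.
#' @param group_levels Optional explicit ordering of the two group values.
#' @return Object of class `contingency_table`: a 2x2 integer matrix with
#'   informative dimnames.
#' @export
build_contingency <- function(records, group_by, outcome,
                              group_levels = NULL) {
  g <- records[[group_by]]
  y <- records[[outcome]]
  if (is.null(g) || is.null(y))
    stop("records lack column '", group_by, "' or '", outcome, "'")
  if (is.null(group_levels)) group_levels <- sort(unique(g))
  if (length(group_levels) != 2)
    stop("group_by must yield exactly 2 groups, got ",
         length(group_levels))
  tab <- vapply(group_levels, function(lv)
    c(sum(y[g == lv]), sum(!y[g == lv])), numeric(2))
  tab <- t(tab)
  storage.mode(tab) <- "integer"
  dimnames(tab) <- list(group = as.character(group_levels),
                        outcome = c("yes", "no"))
  structure(tab, class = c("contingency_table", class(tab)))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Default is the uncorrected Pearson statistic
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with p from the
#' chi-square distribution on 1 df (this matches common
#' statistics-package output for published 2x2 comparisons); Yates
#' continuity correction is available.
#'
#' @param table 2x2 count matrix (rows groups, columns outcome).
#' @param correction `"none"` (default) or `"yates"`.
#' @return Object of class `chi2_result`: `chi2`, `df`, `p_value`,
#'   `correction`.
#' @export
chi2_2x2 <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  tab <- unclass(table)
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  if (sum(tab) < 1) stop("table is empty")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square statistic is undefined: a table margin is zero")
  ht <- suppressWarnings(
    stats::chisq.test(tab, correct = correction == "yates"))
  structure(list(chi2 = unname(ht$statistic), df = 1L,
                 p_value = unname(ht$p.value), correction = correction),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi-square (df=1, %s correction): chi2 = %.4f, p = %.4f\n",
              x$correction, x$chi2, x$p_value))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' @param table 2x2 count matrix.
#' @return `list(p_value = )`.
#' @export
fisher_2x2 <- function(table) {
  tab <- unclass(table)
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  list(p_value = stats::fisher.test(tab)$p.value)
}

#' Summarize a cohort's cell records as a condition-by-condition table
#'
#' Produces one row per (coculture, day, decoupler) condition with FOV,
#' contraction, transient and coupling counts, plus totals by decoupler, by
#' day, and overall. Totals are exact column sums of the constituent rows
#' and invariant to record order.
#'
#' @param records Data frame of per-FOV records.
#' @return Object of class `cohort_summary`: `list(by_condition, totals)`
#'   data frames. `totals$level` distinguishes `decoupler:`/`day:`/`all`
#'   rows.
#' @export
summarize_cohort <- function(records) {
  count_cols <- c(contracting = "n_contr",
                  hipsc_transients_unpaced = "n_hipsc_unpaced",
                  transients_unpaced = "n_adult_unpaced",
                  hipsc_transients_paced = "n_hipsc_paced",
                  transients_paced = "n_adult_paced",
                  coupled = "n_coupled")
  sum_rows <- function(idx) {
    out <- data.frame(n_fov = length(idx))
    for (src in names(count_cols))
      out[[count_cols[[src]]]] <- sum(records[[src]][idx], na.rm = TRUE)
    out
  }
  key <- interaction(records$coculture, records$day, records$nbleb,
                     drop = TRUE)
  parts <- lapply(levels(key), function(lv) {
    idx <- which(key == lv)
    cbind(data.frame(coculture = records$coculture[idx[1]],
                     day = records$day[idx[1]],
                     nbleb = records$nbleb[idx[1]]),
          sum_rows(idx))
  })
  by_condition <- do.call(rbind, parts)
  by_condition <- by_condition[order(by_condition$coculture,
                                     by_condition$day, by_condition$nbleb), ]
  rownames(by_condition) <- NULL
  tot <- rbind(
    cbind(level = "decoupler:none", sum_rows(which(!records$nbleb))),
    cbind(level = "decoupler:nbleb", sum_rows(which(records$nbleb))),
    cbind(level = "day:0", sum_rows(which(records$day == 0))),
    cbind(level = "day:1", sum_rows(which(records$day == 1))),
    cbind(level = "all", sum_rows(seq_len(nrow(records)))))
  pct <- function(n, d) ifelse(d > 0, 100 * n / d, NA_real_)
  tot$pct_coupled <- pct(tot$n_coupled, tot$n_fov)
  tot$pct_contr <- pct(tot$n_contr, tot$n_fov)
  structure(list(by_condition = by_condition, totals = tot),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Per-condition counts:\n")
  print(x$by_condition)
  cat("\nTotals:\n")
  print(x$totals)
  invisible(x)
}

#' Chi-square comparison report over a set of contingency analyses
#'
#' Each comparison names a grouping column and an outcome column of the
#' records; the report lists the 2x2 counts, the chi-square statistic, the
#' p-value rounded to 4 decimal places, and a significance flag at `alpha`.
#'
#' @param records Data frame of per-FOV records.
#' @param comparisons List of `list(group_by =, outcome =)` entries (or
#'   character vector of `group_by` names with `outcome = "coupled"`).
#' @param alpha Significance level.
#' @param correction Passed to [chi2_2x2()].
#' @return Data frame of class `comparison_report` with one row per
#'   comparison (zero rows for an empty comparison list).
#' @export
report <- function(records, comparisons, alpha = 0.05,
                   correction = "none") {
  if (is.character(comparisons))
    comparisons <- lapply(comparisons, function(g)
      list(group_by = g, outcome = "coupled"))
  rows <- lapply(comparisons, function(cmp) {
    tab <- build_contingency(records, cmp$group_by, cmp$outcome)
    res <- chi2_2x2(tab, correction)
    data.frame(group_by = cmp$group_by, outcome = cmp$outcome,
               a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
               chi2 = res$chi2, p_value = round(res$p_value, 4),
               significant = res$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_by = character(0), outcome = character(0),
               a = integer(0), b = integer(0), c = integer(0),
               d = integer(0), chi2 = numeric(0), p_value = numeric(0),
               significant = logical(0))
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Write a comparison report to CSV
#'
#' @param x A `comparison_report`.
#' @param path Output path.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
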