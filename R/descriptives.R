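#' Moment summaries of analysis variables
#'
#' Mean, sample variance (denominator n-1), standard deviation,
#' skewness and kurtosis for each requested variable.  Skewness and
#' kurtosis are the standardised third and fourth central moments
#' (denominator n); kurtosis is *not* excess-corrected, so a normal
#' shape reads about 3.  Constant variables get variance 0 and `NA`
#' skewness/kurtosis.
#'
#' @param table data.frame/data.table of numeric or 0/1-encoded columns.
#' @param variables character vector of column names (default: all
#'   numeric columns).
#' @return data.table `variable`, `mean`, `variance`, `sd`, `skewness`,
#'   `kurtosis`, `n`.
#' @export
summarize_variables <- function(table, variables = NULL) {
  dt <- data.table::as.data.table(table)
  if (is.null(variables))
    variables <- names(dt)[vapply(dt, is.numeric, logical(1))]
  if (length(miss <- setdiff(variables, names(dt))))
    stopf("unknown variable(s): %s", paste(miss, collapse = ", "))
  rows <- lapply(variables, function(v) {
    x <- as.numeric(dt[[v]])
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2)
      return(data.table::data.table(variable = v, mean = mean(x),
                                    variance = NA_real_, sd = NA_real_,
                                    skewness = NA_real_, kurtosis = NA_real_,
                                    n = n))
    m <- mean(x)
    v2 <- sum((x - m)^2) / n          # population moments for shape
    s2 <- v2 * n / (n - 1)            # sample variance
    if (v2 == 0) {
      sk <- ku <- NA_real_
    } else {
      sk <- sum((x - m)^3) / n / v2^1.5
      ku <- sum((x - m)^4) / n / v2^2
    }
    data.table::data.table(variable = v, mean = m, variance = s2,
                           sd = sqrt(s2), skewness = sk, kurtosis = ku, n = n)
  })
  data.table::rbindlist(rows)
}

#' Morbidity prevalence by undesiredness category
#'
#' For one binary outcome and each excess category, reports the percent
#' of outcome-positive children among flagged (`Yes`) and unflagged
#' (`No`) children, with denominators, and additionally the split of the
#' outcome-positive children across the two flag groups (which sums to
#' 100 within a category - the published table layout).
#'
#' @param data table holding the outcome column and the flag columns.
#' @param outcome name of the binary outcome column.
#' @param categories flag columns to stratify by (default the four
#'   excess categories).
#' @return data.table with one row per category: `pct_pos_flagged`,
#'   `pct_pos_unflagged`, `n_flagged`, `n_unflagged`,
#'   `share_flagged_among_pos`, `share_unflagged_among_pos`, `n_pos`.
#'   Empty strata yield `NA` percentages with a zero denominator.
#' @export
prevalence_by_excess <- function(data, outcome,
                                 categories = c("excess_boys",
                                                "excess_girls",
                                                "excess_dual",
                                                "excess_parity")) {
  dt <- data.table::as.data.table(data)
  if (!outcome %in% names(dt)) stopf("outcome column '%s' missing", outcome)
  if (length(miss <- setdiff(categories, names(dt))))
    stopf("flag column(s) missing: %s", paste(miss, collapse = ", "))
  keep <- !is.na(dt[[outcome]])
  y <- dt[[outcome]][keep]
  rows <- lapply(categories, function(cc) {
    f <- dt[[cc]][keep]
    n1 <- sum(f == 1); n0 <- sum(f == 0)
    p1 <- sum(y == 1 & f == 1); p0 <- sum(y == 1 & f == 0)
    npos <- p1 + p0
    data.table::data.table(
      outcome = outcome, category = cc,
      pct_pos_flagged = if (n1 > 0) 100 * p1 / n1 else NA_real_,
      pct_pos_unflagged = if (n0 > 0) 100 * p0 / n0 else NA_real_,
      n_flagged = n1, n_unflagged = n0,
      share_flagged_among_pos = if (npos > 0) 100 * p1 / npos else NA_real_,
      share_unflagged_among_pos = if (npos > 0) 100 * p0 / npos else NA_real_,
      n_pos = npos)
  })
  data.table::rbindlist(rows)
}

#' Undesiredness prevalence by background characteristic
#'
#' For each level of a background variable, the percent of records
#' flagged in each excess category plus the level total - the layout of
#' the published socioeconomic cross-tabulations.  Denominators are
#' child-level records.  Unknown levels (not in `levels`, when given)
#' are collected under `"other"` with a warning.
#'
#' @param data table holding the flag columns and `background_var`.
#' @param background_var name of the categorical column.
#' @param categories flag columns (default the four excess categories).
#' @param levels optional expected level set.
#' @return data.table: `level`, one percent column per category, `n`.
#' @export
crosstab_background <- function(data, background_var,
                                categories = c("excess_boys",
                                               "excess_girls",
                                               "excess_dual",
                                               "excess_parity"),
                                levels = NULL) {
  dt <- data.table::as.data.table(data)
  if (!background_var %in% names(dt))
    stopf("background column '%s' missing", background_var)
  if (length(miss <- setdiff(categories, names(dt))))
    stopf("flag column(s) missing: %s", paste(miss, collapse = ", "))
  lv <- as.character(dt[[background_var]])
  if (!is.null(levels)) {
    unknown <- !(lv %in% as.character(levels)) & !is.na(lv)
    if (any(unknown)) {
      warnf("%d record(s) with unknown '%s' level collected under 'other'",
            sum(unknown), background_var)
      lv[unknown] <- "other"
    }
  }
  dt[, .level := lv]
  out <- dt[, c(list(n = .N),
                lapply(.SD, function(x) 100 * mean(x == 1))),
            by = ".level", .SDcols = categories]
  data.table::setnames(out, ".level", "level")
  data.table::setcolorder(out, c("level", categories, "n"))
  data.table::setorder(out, level)
  out[]
}
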