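# Report emitters: the four reference tables and the figure data series,
# as data frames and as CSV/JSON files. Figures are emitted as (grid, value)
# data series, not rendered images — downstream plotting is trivial and the
# numbers are the deliverable.

report_kinds <- c("table1", "table2", "table3", "table4",
                  "fig1", "fig2", "fig3c", "fig3d")

triangular_df <- function(mat) {
  df <- data.frame(M = as.integer(rownames(mat)), mat, check.names = FALSE)
  names(df) <- c("M", paste0("N", colnames(mat)))
  rownames(df) <- NULL
  df
}

#' Generate a reference table or figure data series
#'
#' Dispatches to the computational modules and returns the requested
#' artifact as a data frame, optionally writing it with [write_report()].
#' With default parameters the four tables reproduce the published
#' reference tables cell-for-cell after each table's stated rounding:
#'
#' * `table1` / `table2`: lower bound of typicality gamma_c in percent
#'   (two- and one-sided 95% intervals; alpha = 0.05, beta = 1), rounded
#'   half-up to 0.1 percentage point.
#' * `table3` / `table4`: one-sided p-values for the majority-null
#'   (gamma0 = 0.5) and global-null (gamma0 = 0) hypotheses, rounded per
#'   [format_pvalue()].
#' * `fig1`: single-outlier error curves delta(omega) for 1-oo-1 and
#'   2-oo-3 and their difference, in percent, on an omega grid.
#' * `fig2`: exact two-sided 95% confidence belts for the significance
#'   rate p and the typicality gamma, for M = 1, 2, 3, 4, 5, 10.
#' * `fig3c`: one-sided gamma_c versus the false-positive rate alpha
#'   (beta = 1) for the 2-oo-2 and 2-oo-3 tallies.
#' * `fig3d`: one-sided gamma_c versus the sensitivity beta
#'   (alpha = 0.01) for the same tallies.
#'
#' @param which One of `"table1"`, `"table2"`, `"table3"`, `"table4"`,
#'   `"fig1"`, `"fig2"`, `"fig3c"`, `"fig3d"`.
#' @param output Optional path; when given the artifact is written there.
#' @param format Output format, `"csv"` or `"json"`.
#' @param alpha,beta Per-subject test characteristics. `NULL` selects the
#'   report's default (alpha 0.05 except `fig3d` which fixes alpha at 0.01;
#'   beta 1).
#' @param level Confidence level for interval-based reports.
#' @param m_max Table size (tables 1-4).
#' @param grid Numeric grid override: omega values for `fig1`, alpha values
#'   for `fig3c`, beta values for `fig3d`.
#' @param verbose Log parameters and package version via [message()].
#' @return The artifact as a data frame (invisibly if `output` is given).
#' @examples
#' run_report("table2")[5, "N5"] # 52.6
#' @export
run_report <- function(which, output = NULL, format = c("csv", "json"),
                       alpha = NULL, beta = NULL, level = 0.95, m_max = 10,
                       grid = NULL, verbose = FALSE) {
  which <- match.arg(which, report_kinds)
  format <- match.arg(format)
  alpha <- if (is.null(alpha)) (if (which == "fig3d") 0.01 else 0.05) else alpha
  beta <- if (is.null(beta)) 1 else beta
  if (which != "fig3d" || !is.null(grid)) check_characteristics(alpha, beta)
  level <- check_prob(level, "level", lower_open = TRUE, upper_open = TRUE)

  df <- switch(which,
    table1 = triangular_df(round_half_up(
      gamma_table(m_max, alpha, beta, level, "two.sided"), 1)),
    table2 = triangular_df(round_half_up(
      gamma_table(m_max, alpha, beta, level, "one.sided"), 1)),
    table3 = triangular_df(format_pvalue(
      pvalue_table(m_max, gamma0 = 0.5, alpha = alpha, beta = beta))),
    table4 = triangular_df(format_pvalue(
      pvalue_table(m_max, gamma0 = 0, alpha = alpha, beta = beta))),
    fig1 = {
      omega <- if (is.null(grid)) seq(0, 0.49, by = 0.01) else grid
      data.frame(
        omega_percent = 100 * omega,
        typicality_percent = 100 * (1 - omega),
        delta_1oo1_percent = 100 * delta_curve(1, omega),
        delta_2oo3_percent = 100 * delta_curve(3, omega),
        difference_percent = 100 * delta_difference(omega))
    },
    fig2 = {
      rows <- do.call(rbind, lapply(c(1:5, 10), function(m) {
        do.call(rbind, lapply(0:m, function(n) {
          ci <- proportion_interval(n, m, level, "two.sided")
          data.frame(M = m, N = n, ratio = n / m,
                     p_lower_percent = 100 * ci$lower,
                     p_upper_percent = 100 * ci$upper,
                     gamma_lower_percent =
                       100 * gamma_from_p(ci$lower, alpha, beta),
                     gamma_upper_percent =
                       100 * gamma_from_p(ci$upper, alpha, beta))
        }))
      }))
      rownames(rows) <- NULL
      rows
    },
    fig3c = {
      a <- if (is.null(grid)) exp(seq(log(1e-6), log(0.05), length.out = 50))
           else grid
      data.frame(
        alpha = a,
        gamma_c_2oo2_percent =
          100 * gamma_sensitivity(2, 2, a, beta, level, "one.sided")$gamma_c,
        gamma_c_2oo3_percent =
          100 * gamma_sensitivity(2, 3, a, beta, level, "one.sided")$gamma_c)
    },
    fig3d = {
      b <- if (is.null(grid)) seq(0.5, 1, by = 0.01) else grid
      data.frame(
        beta = b,
        gamma_c_2oo2_percent =
          100 * gamma_sensitivity(2, 2, alpha, b, level, "one.sided")$gamma_c,
        gamma_c_2oo3_percent =
          100 * gamma_sensitivity(2, 3, alpha, b, level, "one.sided")$gamma_c)
    })

  if (verbose) {
    message(sprintf(
      "typicality %s: report %s (alpha = %g, beta = %g, level = %g, m_max = %d)",
      as.character(utils::packageVersion("typicality")), which, alpha, beta,
      level, m_max))
  }
  if (!is.null(output)) {
    write_report(df, output, format)
    return(invisible(df))
  }
  df
}

#' Write a report data frame to CSV or JSON
#'
#' CSV is comma-separated, period decimal mark, UTF-8, with a header row;
#' JSON is an array of row records. Percent-scale columns are already on
#' the percent scale, matching the reference tables.
#'
#' @param df A data frame, typically from [run_report()].
#' @param output Destination path.
#' @param format `"csv"` or `"json"`.
#' @return `output`, invisibly.
#' @export
write_report <- function(df, output, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(df, output, row.names = FALSE, fileEncoding = "UTF-8",
                     na = "")
  } else {
    jsonlite::write_json(df, output, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(output)
}
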