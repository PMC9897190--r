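#' Tremor improvement fraction
#'
#' \code{(pre - post) / pre} on a pre/post tremor rating-scale pair (the
#' spiral-based WHIGET score in the source cohort). A negative value means
#' worsening and is returned with a warning.
#'
#' @param pre pre-treatment score (> 0).
#' @param post post-treatment score (>= 0).
#' @return improvement fraction in (-Inf, 1].
#' @export
tremor_improvement <- function(pre, post) {
  stopifnot(is.numeric(pre), is.numeric(post), pre >= 0, post >= 0)
  if (any(pre == 0))
    stop("undefined-improvement error: pre-treatment score is 0", call. = FALSE)
  out <- (pre - post) / pre
  if (any(out < 0)) warning("negative improvement: post-treatment score exceeds pre")
  out
}

#' The bundled treatment-cohort case table
#'
#' Eighteen consecutive essential-tremor cases: indirect target, first and
#' second tractography/sonication target coordinates (AC-PC mm) and the
#' published Euclidean-distance column, with provenance notes where the
#' printed values carry ambiguities.
#'
#' @param path override the bundled fixture path (for testing).
#' @return list with \code{cases} (data.frame), \code{convention},
#'   \code{printed_average_row}, \code{notes}.
#' @export
table1_cases <- function(path = system.file("extdata", "table1_cases.json",
                                            package = "fourtract")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cases <- do.call(rbind, lapply(raw$cases, function(cs) {
    t2 <- cs$target2
    data.frame(case = cs$case, side = cs$side,
               ind_L = cs$indirect$L, ind_A = cs$indirect$A, ind_S = cs$indirect$S,
               t1_L = cs$target1$L, t1_A = cs$target1$A, t1_S = cs$target1$S,
               t2_L = if (is.null(t2)) NA_real_ else t2$L,
               t2_A = if (is.null(t2)) NA_real_ else t2$A,
               t2_S = if (is.null(t2)) NA_real_ else t2$S,
               printed_offset_mm = cs$printed_offset_mm,
               notes = if (is.null(cs$notes)) "" else cs$notes)
  }))
  list(cases = cases, convention = raw$convention,
       printed_average_row = raw$printed_average_row,
       description = raw$description)
}

round_half_up <- function(x, digits) {
  ## table-style rounding (0.5 away from zero), stable across platforms
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort report: target offsets and coordinate statistics
#'
#' Recomputes, for every case, the Euclidean offset between the indirect
#' target and the first tractography target under the table convention (the
#' indirect target taken at S = \code{indirect_s} mm), and summarizes the
#' cohort: mean and sample SD (n - 1) of the offsets and of each coordinate
#' column, and paired t tests of the indirect versus first-target A and L
#' coordinates. Cases without a second target are excluded from the
#' second-target column statistics (n = 17 in the bundled cohort).
#'
#' @param cases data.frame as returned in \code{table1_cases()$cases}, or
#'   NULL for the bundled cohort.
#' @param indirect_s S convention for the offset computation, mm.
#' @return object of class \code{cohort_report}: \code{per_case} (with
#'   computed and, if available, printed offsets), \code{summary} (means and
#'   SDs), \code{paired_t} (A and L statistics), \code{n}.
#' @export
cohort_report <- function(cases = NULL, indirect_s = 2) {
  if (is.null(cases)) cases <- table1_cases()$cases
  if (NROW(cases) < 2) stop("validation error: need at least 2 cases", call. = FALSE)
  off <- sqrt((cases$ind_L - cases$t1_L)^2 + (cases$ind_A - cases$t1_A)^2 +
              (indirect_s - cases$t1_S)^2)
  per_case <- data.frame(case = cases$case,
                         offset_mm = round_half_up(off, 2))
  if (!is.null(cases$printed_offset_mm)) {
    per_case$printed_offset_mm <- cases$printed_offset_mm
    per_case$matches_printed <-
      abs(per_case$offset_mm - cases$printed_offset_mm) < 5e-3
  }
  if (!is.null(cases$notes)) per_case$notes <- cases$notes
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = round_half_up(mean(x), 1), sd = round_half_up(stats::sd(x), 1),
      n = length(x))
  }
  summ <- rbind(indirect_L = msd(cases$ind_L), indirect_A = msd(cases$ind_A),
                target1_L = msd(cases$t1_L), target1_A = msd(cases$t1_A),
                target1_S = msd(cases$t1_S),
                target2_L = msd(cases$t2_L), target2_A = msd(cases$t2_A),
                target2_S = msd(cases$t2_S),
                offset = c(mean = round_half_up(mean(off), 2),
                           sd = round_half_up(stats::sd(off), 2),
                           n = length(off)))
  safe_t <- function(x, y) {
    tryCatch(stats::t.test(x, y, paired = TRUE),
             error = function(e) list(statistic = NA_real_,
                                      parameter = length(x) - 1,
                                      p.value = NA_real_,
                                      estimate = mean(x - y)))
  }
  tA <- safe_t(cases$t1_A, cases$ind_A)
  tL <- safe_t(cases$t1_L, cases$ind_L)
  structure(list(per_case = per_case,
                 summary = as.data.frame(summ),
                 offset_mean_raw = mean(off),
                 printed_column_mean = if (!is.null(cases$printed_offset_mm))
                   mean(cases$printed_offset_mm) else NA_real_,
                 paired_t = data.frame(
                   coordinate = c("A", "L"),
                   t = c(unname(tA$statistic), unname(tL$statistic)),
                   df = c(unname(tA$parameter), unname(tL$parameter)),
                   p_value = c(tA$p.value, tL$p.value),
                   mean_diff = c(unname(tA$estimate), unname(tL$estimate))),
                 indirect_s = indirect_s,
                 n = NROW(cases)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d cases (indirect target taken at S = %g mm)\n",
              x$n, x$indirect_s))
  cat("\nPer-case indirect -> first-target offsets (mm):\n")
  print(x$per_case, row.names = FALSE)
  cat("\nCohort summary (mean, sample SD):\n")
  print(x$summary)
  if (!is.na(x$printed_column_mean))
    cat(sprintf("\nmean of recomputed offsets: %.2f mm; mean of printed column: %.2f mm\n",
                x$offset_mean_raw, x$printed_column_mean))
  cat("\nPaired t, indirect vs first tractography target:\n")
  pt <- x$paired_t
  for (i in seq_len(nrow(pt)))
    cat(sprintf("  %s: mean diff %+.2f mm, t(%d) = %.2f, P = %.4g\n",
                pt$coordinate[i], pt$mean_diff[i], pt$df[i], pt$t[i],
                pt$p_value[i]))
  invisible(x)
}

#' Write a cohort report as a tab-separated table
#' @param report a \code{cohort_report}.
#' @param path output .tsv path; a companion .json is written alongside.
#' @return invisibly, the paths written.
#' @export
write_cohort_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  utils::write.table(report$per_case, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jpath <- sub("\\.tsv$", ".json", path)
  if (identical(jpath, path)) jpath <- paste0(path, ".json")
  jsonlite::write_json(list(summary = cbind(stat = rownames(report$summary),
                                            report$summary),
                            paired_t = report$paired_t,
                            offset_mean_raw = report$offset_mean_raw,
                            n = report$n),
                       jpath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(path, jpath))
}
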