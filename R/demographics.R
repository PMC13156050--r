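# Group comparisons of demographic variables, from raw rows or printed
# summary statistics.

welch_or_pooled <- function(m1, s1, n1, m2, s2, n2, var_ratio_threshold) {
  if (n1 < 2L || n2 < 2L) stop_invalid("each group needs at least 2 observations")
  v1 <- s1^2; v2 <- s2^2
  ratio <- max(v1, v2) / min(v1, v2)
  if (ratio >= var_ratio_threshold) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    test <- "welch"
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    test <- "pooled"
  }
  t <- if (se == 0) 0 else (m1 - m2) / se
  if (se == 0) df <- n1 + n2 - 2
  list(test = test, statistic = t, df = df,
       p = if (se == 0) 1 else 2 * pt(-abs(t), df = df), var_ratio = ratio)
}

#' Group demographic comparisons
#'
#' Compares patient and control demographics: two-sample t-tests for the
#' continuous variables — unequal-variance (Welch) when the ratio of the
#' larger to the smaller sample variance reaches `var_ratio_threshold`,
#' pooled otherwise — and a Pearson chi-square test without continuity
#' correction for sex. The computation is identical whether it starts from
#' raw cohort rows or from printed group summaries (mean, SD, n).
#'
#' @param cohort optional data.frame with `group`, `age`, `sex`, `education`,
#'   `tiv` columns (raw mode).
#' @param summaries optional list (summary mode) with elements `continuous`
#'   (data.frame: `variable`, `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`;
#'   group 1 = patients) and `sex` (2 x 2 count matrix, groups in rows,
#'   M/F in columns).
#' @param var_ratio_threshold variance-ratio gate for Welch vs pooled
#'   (default 1.3).
#' @return data.frame of class `cc_demographics`: `variable`, `test`,
#'   `statistic`, `df`, `p`.
#' @examples
#' demographics(summaries = example_cohort_summaries())
#' @export
demographics <- function(cohort = NULL, summaries = NULL,
                         var_ratio_threshold = 1.3) {
  if (is.null(cohort) == is.null(summaries))
    stop_invalid("supply exactly one of cohort or summaries")
  if (!is.null(cohort)) {
    g <- as.character(cohort$group)
    lev <- sort(unique(g))
    if (length(lev) != 2L) stop_invalid("cohort must contain exactly 2 groups")
    pat_lev <- if ("patient" %in% lev) "patient" else lev[2]
    pat <- cohort[g == pat_lev, ]
    ctl <- cohort[g != pat_lev, ]
    vars <- intersect(c("age", "education", "tiv"), names(cohort))
    continuous <- do.call(rbind, lapply(vars, function(v) {
      data.frame(variable = v,
                 mean1 = mean(pat[[v]]), sd1 = sd(pat[[v]]), n1 = nrow(pat),
                 mean2 = mean(ctl[[v]]), sd2 = sd(ctl[[v]]), n2 = nrow(ctl))
    }))
    sex_tab <- rbind(patient = table(factor(pat$sex, levels = c("M", "F"))),
                     control = table(factor(ctl$sex, levels = c("M", "F"))))
    summaries <- list(continuous = continuous, sex = sex_tab)
  }
  cont <- summaries$continuous
  rows <- lapply(seq_len(nrow(cont)), function(i) {
    r <- welch_or_pooled(cont$mean1[i], cont$sd1[i], cont$n1[i],
                         cont$mean2[i], cont$sd2[i], cont$n2[i],
                         var_ratio_threshold)
    data.frame(variable = cont$variable[i], test = r$test,
               statistic = r$statistic, df = r$df, p = r$p)
  })
  out <- do.call(rbind, rows)
  if (!is.null(summaries$sex)) {
    cs <- suppressWarnings(stats::chisq.test(as.matrix(summaries$sex), correct = FALSE))
    out <- rbind(out, data.frame(variable = "sex", test = "chi-square",
                                 statistic = unname(cs$statistic),
                                 df = unname(cs$parameter), p = cs$p.value))
  }
  class(out) <- c("cc_demographics", class(out))
  out
}

#' Bundled example demographic summaries
#'
#' Printed group summary statistics for a schizophrenia case-control sample
#' (151 patients, 278 controls), used in examples and as a worked input for
#' the summary mode of [demographics()]: age, years of education and total
#' intracranial volume as mean/SD per group, plus the 2 x 2 sex table.
#'
#' @return list with elements `continuous` (data.frame) and `sex` (2 x 2
#'   matrix), in the format [demographics()] expects.
#' @export
example_cohort_summaries <- function() {
  list(
    continuous = data.frame(
      variable = c("age", "education", "tiv"),
      mean1 = c(20.34, 11.27, 1449.59), sd1 = c(6.93, 2.81, 127.23), n1 = 151L,
      mean2 = c(23.71, 15.09, 1446.47), sd2 = c(5.95, 3.17, 123.79), n2 = 278L,
      stringsAsFactors = FALSE
    ),
    sex = matrix(c(59L, 92L, 92L, 186L), nrow = 2, byrow = TRUE,
                 dimnames = list(c("patient", "control"), c("M", "F")))
  )
}
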