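# Case-control descriptive comparison machinery: percentages, two-sample
# tests, and the per-group characteristics table.

#' Percentage to one decimal
#'
#' @param count numerator (0 <= count <= total).
#' @param total positive denominator.
#' @return \code{100 * count / total} rounded to 1 decimal.
#' @examples percent(92, 116)  # 79.3
#' @export
percent <- function(count, total) {
  if (any(total <= 0) || any(count < 0) || any(count > total))
    stop("need 0 <= count <= total with total > 0")
  round(100 * count / total, 1)
}

#' Two-sample t test from summary statistics
#'
#' Welch's unequal-variance t by default, with the Welch-Satterthwaite
#' degrees of freedom; \code{pooled = TRUE} gives the classical
#' equal-variance Student t.  Operates on summaries (means, SDs, sizes), as
#' needed when comparing published table cells.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (n >= 2, sd > 0).
#' @param pooled use the pooled-variance Student t.
#' @return list: \code{t}, \code{df}, \code{p} (two-sided).
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 <= 0 || sd2 <= 0) stop("need positive SDs")
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed form \eqn{n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, no continuity
#' correction; p from the chi-square distribution with 1 df.
#'
#' @param a,b,c,d cell counts (first row a, b; second row c, d); both
#'   margins must be positive.
#' @return list: \code{statistic}, \code{p}.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) stop("both margins must be positive")
  stat <- n * (a * d - b * c)^2 / prod(m)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value summing the hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed
#' table (the \code{\link[stats]{fisher.test}} convention).  A table with a
#' zero margin has p = 1.
#'
#' @inheritParams chi_square_2x2
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact enumeration when both samples are small (n <= 20) and untied;
#' otherwise the normal approximation with midranks and the tie correction
#' (no continuity correction).  The statistic U counts pairs where x exceeds
#' y (midranks contribute 1/2).
#'
#' @param x,y numeric samples, both nonempty.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return list: \code{U}, \code{p}.
#' @export
wilcoxon_mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && max(length(x), length(y)) <= 20L
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

.fmt_mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x), sd(x))
.fmt_n_pct <- function(k, n) sprintf("%d (%.1f)", k, percent(k, n))

# choose chi-square unless any expected cell < 5, then Fisher
.freq_test <- function(a, b, c, d) {
  n <- a + b + c + d
  expd <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  if (any(expd < 5)) list(test = "fisher", p = fisher_exact(a, b, c, d))
  else list(test = "chi-square", p = chi_square_2x2(a, b, c, d)$p)
}

#' Descriptive case-control comparison table
#'
#' Per race/ethnicity group, case-vs-control summaries and tests for age,
#' sex, smoking, BMI, vitamin D supplement use, season of blood draw and
#' HLA-DRB1*15:01 carriage: Welch t for continuous variables, chi-square
#' (or Fisher exact when any expected cell is below 5) for frequencies.
#' Variables with a single observed level are summarised without a test.
#'
#' @param participants participant table of a \code{cohort_bundle}.
#' @param serum serum table (for the season of the 25OHD draw).
#' @return data frame: \code{group}, \code{variable}, \code{cases},
#'   \code{controls}, \code{test}, \code{p_value}.
#' @export
table_one <- function(participants, serum) {
  season <- serum$season %||% draw_season(serum$draw_date)
  season <- season[match(participants$id, serum$participant_id)]
  rows <- list()
  for (g in unique(participants$group)) {
    p <- participants[participants$group == g, , drop = FALSE]
    sg <- season[participants$group == g]
    ca <- p$role == "case"
    n1 <- sum(ca)
    n0 <- sum(!ca)
    add <- function(variable, cases, controls, test, p_value)
      rows[[length(rows) + 1L]] <<- data.frame(
        group = g, variable = variable, cases = cases, controls = controls,
        test = test, p_value = p_value, stringsAsFactors = FALSE)
    cont <- function(label, v) {
      if (sd(v[ca]) == 0 || sd(v[!ca]) == 0) {
        add(label, .fmt_mean_sd(v[ca]), .fmt_mean_sd(v[!ca]), "none",
            NA_real_)
      } else {
        tt <- two_sample_t(mean(v[ca]), sd(v[ca]), n1,
                           mean(v[!ca]), sd(v[!ca]), n0)
        add(label, .fmt_mean_sd(v[ca]), .fmt_mean_sd(v[!ca]), "welch-t", tt$p)
      }
    }
    bin <- function(label, flag) {
      a <- sum(flag[ca]); b <- n1 - a
      c_ <- sum(flag[!ca]); d <- n0 - c_
      if (a + c_ == 0L || b + d == 0L) {
        add(label, .fmt_n_pct(a, n1), .fmt_n_pct(c_, n0), "none", NA_real_)
      } else {
        ft <- .freq_test(a, b, c_, d)
        add(label, .fmt_n_pct(a, n1), .fmt_n_pct(c_, n0), ft$test, ft$p)
      }
    }
    cont("age_years", age_years(p$birth_date, p$index_date))
    bin("female", p$sex == "F")
    bin("smoking_ever", p$smoking == "ever")
    cont("bmi", p$bmi)
    bin("vitd_supplement", p$supplement_user)
    bin("season_apr_sep", sg == "AprSep")
    bin("hla_drb1_carrier", p$hla_carrier)
  }
  do.call(rbind, rows)
}
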