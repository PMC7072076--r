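# Cohort statistics layer: per-day rank tests, baseline exact tests,
# healthy-control reference bands, subset ANOVA with Tukey follow-up,
# correlation / paired tests, and a normality screen. The longitudinal
# group comparison lives in fit_gee().

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. Uses the exact null
#' distribution of U when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   distribution.
#' @return List with `U` (statistic for `x` vs `y`), `p` (two-sided),
#'   `exact`.
#' @export
mw_u_test <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) {
    exact <- (length(x) + length(y)) <= 12 && !has_ties
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = min(wt$p.value, 1), exact = exact)
}

#' Per-time-point group comparison
#'
#' Mann-Whitney U comparison of one metric between two groups at one study
#' day (the paper-style per-day follow-up to the GEE). A group with no
#' observations at that day yields a flagged missing result, not a test.
#'
#' @param data Cohort table (see [fit_gee()]).
#' @param metric Metric name.
#' @param day Study day.
#' @param groups Length-2 character vector of group labels.
#' @return List with `U`, `p`, `n` (per-group sizes), `missing` (TRUE if
#'   either group is empty at that day).
#' @export
per_timepoint_test <- function(data, metric, day,
                               groups = c("no_infection", "infection")) {
  d <- data[data$metric == metric & data$day == day &
              data$group %in% groups & !is.na(data$value), , drop = FALSE]
  x <- d$value[d$group == groups[1]]
  y <- d$value[d$group == groups[2]]
  if (length(x) == 0 || length(y) == 0) {
    return(list(U = NA_real_, p = NA_real_,
                n = c(length(x), length(y)), missing = TRUE))
  }
  res <- mw_u_test(x, y)
  c(res[c("U", "p")], list(n = c(length(x), length(y)), missing = FALSE))
}

#' Baseline-table tests
#'
#' The baseline-characteristics comparison between outcome groups:
#' categorical variables as a 2 x k count table tested with Fisher's exact
#' test (the Freeman-Halton extension for k > 2), continuous covariates
#' with the Mann-Whitney U machinery. Two-sided p-values sum the
#' probabilities of all tables as or less probable than the observed one.
#'
#' @param x A count matrix (2 rows), or a numeric sample.
#' @param y Second numeric sample when `x` is numeric.
#' @return List with `p` and `method`; for continuous input also `U`.
#' @export
baseline_tests <- function(x, y = NULL) {
  if (is.matrix(x)) {
    if (any(x < 0) || any(x != round(x))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
      stop("empty margin in the contingency table", call. = FALSE)
    }
    p <- stats::fisher.test(x)$p.value
    return(list(p = min(p, 1), method = "fisher_exact"))
  }
  res <- mw_u_test(x, y)
  list(U = res$U, p = res$p, method = "mann_whitney")
}

#' Healthy-control reference band
#'
#' The 95% confidence interval of the healthy-control mean:
#' `mean +/- t(0.975, n-1) * SD / sqrt(n)`, shown as the gray band against
#' which patient trajectories are read.
#'
#' @param values Control measurements of one metric (n >= 2).
#' @param conf Confidence level.
#' @return A `ReferenceBand` list: `lower`, `upper`, `mean`, `n`.
#' @export
reference_band <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("reference band requires at least 2 controls",
                  call. = FALSE)
  m <- mean(values)
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(values) / sqrt(n)
  structure(list(lower = m - half, upper = m + half, mean = m, n = n),
            class = "ReferenceBand")
}

#' Position of a value relative to a reference band
#' @param value Numeric value (e.g. a patient-group mean).
#' @param band A [reference_band()].
#' @return `"below"`, `"within"` or `"above"`.
#' @export
band_position <- function(value, band) {
  stopifnot(inherits(band, "ReferenceBand"))
  if (value < band$lower) "below"
  else if (value > band$upper) "above"
  else "within"
}

#' One-way ANOVA across neutrophil subsets with Tukey follow-up
#'
#' Compares the 60-minute mean acidification ratio between the three
#' CD16/CD62L subsets across patients: classical one-way ANOVA followed by
#' Tukey's honest significant difference for the pairwise comparisons.
#'
#' @param values Numeric responses.
#' @param subset Factor (or character) of subset labels, 3 levels, each
#'   with n >= 2.
#' @return List with `F`, `p`, `df`, `tukey` (data frame of pairwise
#'   differences and adjusted p-values), `p_floor` (TRUE when within-group
#'   variance is zero and p is reported as 0).
#' @export
subset_anova <- function(values, subset) {
  subset <- factor(subset)
  cnt <- table(subset)
  if (nlevels(subset) != 3) {
    stop("exactly 3 subset groups are required", call. = FALSE)
  }
  if (any(cnt < 2)) {
    stop("every subset group needs n >= 2", call. = FALSE)
  }
  d <- data.frame(value = values, subset = subset)
  fit <- stats::aov(value ~ subset, data = d)
  # a perfect fit (zero within-group variance) is handled explicitly below
  tab <- suppressWarnings(stats::anova(fit))
  Fv <- tab$`F value`[1]
  pv <- tab$`Pr(>F)`[1]
  p_floor <- FALSE
  msw_zero <- tab$`Mean Sq`[2] <= 1e-12 * max(tab$`Mean Sq`[1], 1e-300)
  if (msw_zero) {  # (numerically) zero within-group variance
    Fv <- Inf
    pv <- 0
    p_floor <- TRUE
    tk <- NULL
  } else {
    th <- stats::TukeyHSD(fit)$subset
    tk <- data.frame(comparison = rownames(th), th, row.names = NULL)
    names(tk) <- c("comparison", "diff", "lower", "upper", "p_adj")
  }
  list(F = Fv, p = pv, df = tab$Df, tukey = tk, p_floor = p_floor)
}

#' Spearman rank correlation
#'
#' Tie-corrected Spearman correlation (used for the baseline-covariate
#' versus acidification screen). Constant input has no defined rank
#' correlation and is flagged rather than reported as 0.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p`, `undefined`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, undefined = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = min(ct$p.value, 1), undefined = FALSE)
}

#' Friedman test across repeated within-subject conditions
#'
#' Rank test for paired condition comparisons (e.g. the same controls
#' assayed on ice, at 25 and at 37 degrees C).
#'
#' @param mat Numeric matrix, rows = subjects, columns = conditions
#'   (>= 2 of each).
#' @return List with `statistic` (chi-square), `df`, `p`.
#' @export
friedman_conditions <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("Friedman test needs >= 2 subjects and >= 2 conditions",
         call. = FALSE)
  }
  ft <- stats::friedman.test(mat)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {  # every subject fully tied across conditions
    stat <- 0
    p <- 1
  }
  list(statistic = stat, df = unname(ft$parameter), p = p)
}

#' Shapiro-Wilk normality screen
#'
#' Pass-through contract for the distribution screening step that decides
#' between parametric and rank-based comparisons.
#'
#' @param x Numeric sample (3 to 5000 values).
#' @return List with `W`, `p`.
#' @export
normality_screen <- function(x) {
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}
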