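# Inferential layer: repeated-measures ANOVA with covariates, Bonferroni
# post hoc paired tests with effect sizes, the mixed model for
# anticorrelation, and Steiger's z for dependent overlapping correlations.

#' Repeated-measures ANOVA on a long-format table
#'
#' Within-subject effects (and their interaction, for two factors) with
#' partial eta squared. On a balanced complete design with no covariates
#' the classical within-subject error partitioning is used (via
#' `stats::aov` with a subject error stratum), so a two-condition factor
#' reproduces the paired-t identity F = t^2 exactly. With covariates the
#' model is a subject-random-intercept linear mixed model
#' (`lmerTest::lmer`) with Satterthwaite denominator df.
#'
#' @param table long-format data.frame, one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor column names
#'   (one or two).
#' @param covariates optional character vector of covariate column names
#'   (constant within subject, e.g. age, sex).
#' @param subject name of the subject id column.
#' @return data.frame: effect, F, df1, df2, p, eta_sq (partial eta squared
#'   computed as F df1 / (F df1 + df2)).
#' @export
rm_anova <- function(table, dv, within, covariates = NULL,
                     subject = "subject") {
  table <- as.data.frame(table)
  for (w in within) table[[w]] <- factor(table[[w]])
  table[[subject]] <- factor(table[[subject]])
  # completeness check
  cells <- interaction(table[within], drop = FALSE)
  tab <- table(table[[subject]], cells)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1L, ]
    stopf("incomplete design: subject %s has %d records in cell %s",
          rownames(tab)[bad[1L]], tab[bad[1L], bad[2L]], colnames(tab)[bad[2L]])
  }

  if (!is.null(covariates)) {
    # covariates with a single observed level carry no information and
    # would break the model matrix (e.g. a single-sex subsample)
    covariates <- covariates[vapply(covariates, function(cv)
      length(unique(table[[cv]])) > 1L, logical(1))]
    if (!length(covariates)) covariates <- NULL
  }
  fx <- paste(within, collapse = " * ")
  if (is.null(covariates)) {
    f <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))", dv, fx, subject, fx))
    fit <- stats::aov(f, data = table)
    sm <- summary(fit)
    rows <- list()
    for (stratum in sm) {
      a <- stratum[[1L]]
      eff <- trimws(rownames(a))
      for (i in seq_len(nrow(a))) {
        if (eff[i] == "Residuals") next
        df2 <- a["Residuals", "Df"]
        rows[[length(rows) + 1L]] <- data.frame(
          effect = eff[i], F = a[i, "F value"], df1 = a[i, "Df"], df2 = df2,
          p = a[i, "Pr(>F)"], stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
  } else {
    rhs <- paste(c(fx, covariates), collapse = " + ")
    f <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", dv, rhs, subject))
    fit <- lmerTest::lmer(f, data = table,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
    a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    keep <- !(rownames(a) %in% covariates)
    out <- data.frame(effect = rownames(a)[keep], F = a[keep, "F value"],
                      df1 = a[keep, "NumDF"], df2 = a[keep, "DenDF"],
                      p = a[keep, "Pr(>F)"], stringsAsFactors = FALSE)
  }
  out$eta_sq <- out$F * out$df1 / (out$F * out$df1 + out$df2)
  rownames(out) <- NULL
  out
}

#' Paired t-test with Bonferroni correction and Cohen's d
#'
#' `d` is the paired (d_z) variant: mean of differences over sd of
#' differences. Pairs with an undefined value in either member are dropped
#' with the count reported.
#'
#' @param a,b per-subject values, paired by position.
#' @param m_comparisons Bonferroni family size (corrected p = min(1, p m)).
#' @return data.frame: t, df, p, p_corrected, d, n, n_dropped.
#' @export
paired_t <- function(a, b, m_comparisons = 1L) {
  if (length(a) != length(b)) stopf("paired vectors differ in length")
  keep <- is.finite(a) & is.finite(b)
  n_dropped <- sum(!keep)
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 3L) stopf("need >= 3 complete pairs, have %d", n)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0))  # identical vectors: no evidence of any difference
      return(data.frame(t = 0, df = n - 1L, p = 1, p_corrected = 1, d = 0,
                        n = n, n_dropped = n_dropped))
    stopf("degenerate input: all pairwise differences equal and nonzero")
  }
  t <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(t), df = n - 1L, lower.tail = FALSE)
  data.frame(t = t, df = n - 1L, p = p,
             p_corrected = min(1, p * m_comparisons),
             d = mean(d) / sdd, n = n, n_dropped = n_dropped)
}

#' Bonferroni-adjusted alpha
#'
#' @param family_alpha family-wise alpha in (0, 1].
#' @param m number of comparisons (>= 1).
#' @return per-comparison alpha `family_alpha / m`.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) stopf("m must be >= 1")
  if (family_alpha <= 0 || family_alpha > 1) stopf("family_alpha must be in (0, 1]")
  family_alpha / m
}

#' Mixed model for DMN-DAN anticorrelation
#'
#' Random-intercept model estimating the anticorrelation Fisher z from
#' combined time spent in the DMN and DAN states, controlling for age,
#' sex, drug, and the drug x time interaction. Marginal R^2 is
#' var(fixed) / (var(fixed) + var(subject) + var(residual)); conditional
#' R^2 adds the subject variance to the numerator.
#'
#' @param table data.frame with columns `subject`, `anticorr_z`,
#'   `time_in_state`, `age`, `sex`, `drug` (>= 2 observations per
#'   subject).
#' @return list: `fixed` (coefficient table), `varcomp`, `marginal_r2`,
#'   `conditional_r2`, `fit`.
#' @export
lmm_anticorr <- function(table) {
  table <- as.data.frame(table)
  if (any(table(table$subject) < 2L)) stopf("need >= 2 observations per subject")
  table$drug <- factor(table$drug)
  table$age_c <- table$age - mean(table$age)
  covs <- c("age_c", "sex")
  covs <- covs[vapply(covs, function(cv) length(unique(table[[cv]])) > 1L,
                      logical(1))]
  f <- stats::as.formula(paste(
    c("anticorr_z ~ time_in_state", covs, "drug", "drug:time_in_state",
      "(1 | subject)"), collapse = " + "))
  fit <- lmerTest::lmer(
    f, data = table,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  if (lme4::isSingular(fit))
    warnf("singular fit: subject variance component pinned at 0")
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_subj <- vc$vcov[vc$grp == "subject"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(stats::predict(fit, re.form = NA))
  tot <- var_fixed + var_subj + var_resid
  list(fixed = stats::coef(summary(fit)),
       varcomp = c(subject = var_subj, residual = var_resid),
       marginal_r2 = var_fixed / tot,
       conditional_r2 = (var_fixed + var_subj) / tot,
       fit = fit)
}

#' Steiger's z for two dependent overlapping correlations
#'
#' Compares `r1 = cor(x, y1)` with `r2 = cor(x, y2)` sharing variable x,
#' given `r_y1y2 = cor(y1, y2)`:
#' `z = (atanh(r1) - atanh(r2)) sqrt((n-3) / (2 (1 - s)))` where `s` is
#' the covariance term evaluated at the mean correlation
#' `rbar = (r1 + r2)/2`:
#' `s = (r_y1y2 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r_y1y2^2) / 2) /
#'  (1 - rbar^2)^2`. One-sided p tests r1 > r2.
#'
#' @param r1,r2 correlations with the shared variable.
#' @param r_y1y2 correlation between the two non-shared variables.
#' @param n sample size (>= 4).
#' @param sided `"one"` or `"two"`.
#' @return data.frame: r1, r2, r_y1y2, n, z, p.
#' @export
steiger_z <- function(r1, r2, r_y1y2, n, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (any(abs(c(r1, r2)) >= 1)) stopf("correlations must satisfy |r| < 1")
  if (abs(r_y1y2) > 1) stopf("correlations must satisfy |r| <= 1")
  if (n < 4L) stopf("need n >= 4")
  if (abs(r1 - r2) < 1e-15) {
    # identical correlations (e.g. y2 is y1 itself): no difference to test
    p <- if (sided == "one") 0.5 else 1
    return(data.frame(r1 = r1, r2 = r2, r_y1y2 = r_y1y2, n = n, z = 0, p = p))
  }
  if (abs(r_y1y2) >= 1) stopf("degenerate: y1 and y2 are collinear but r1 != r2")
  rbar <- (r1 + r2) / 2
  s <- (r_y1y2 * (1 - 2 * rbar^2) -
          0.5 * rbar^2 * (1 - 2 * rbar^2 - r_y1y2^2)) / (1 - rbar^2)^2
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - s)))
  p <- if (sided == "one") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(r1 = r1, r2 = r2, r_y1y2 = r_y1y2, n = n, z = z, p = p)
}
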