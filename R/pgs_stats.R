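#' Linear polygenic scoring from a dosage matrix
#'
#' `raw_score = sum_v dosage(sample, v) * effect(v)`, with dosages coded on
#' the effect allele in \[0, 2\]. Missing dosages are imputed as twice the
#' effect-allele frequency computed from the non-missing entries of the
#' input matrix (`missing = "impute"`, the PLINK `--score` default
#' behaviour) or the variant is skipped for that sample
#' (`missing = "skip"`). Weight variants absent from the matrix produce a
#' warning and are skipped; if no weight variant is usable this is an error.
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids)
#' @param weights data.frame with `variant`, `effect_allele`, `effect`
#' @param missing `"impute"` (default) or `"skip"`
#' @return data.frame with `sample_id` and `raw_score`
#' @export
pgs_score <- function(dosages, weights, missing = c("impute", "skip")) {
  missing <- match.arg(missing)
  dosages <- as.matrix(dosages)
  keep <- weights$variant %in% colnames(dosages)
  if (any(!keep))
    warning(sum(!keep), " weight variant(s) absent from dosage matrix; skipped",
            call. = FALSE)
  weights <- weights[keep, , drop = FALSE]
  assert_that(nrow(weights) > 0L, "no usable variants for scoring")
  m <- dosages[, weights$variant, drop = FALSE]
  if (missing == "impute") {
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      if (any(na)) m[na, j] <- mean(m[!na, j])  # 2 * effect-allele frequency
    }
  } else {
    m[is.na(m)] <- 0
  }
  data.frame(sample_id = rownames(dosages),
             raw_score = as.numeric(m %*% weights$effect),
             stringsAsFactors = FALSE)
}

#' Standardize polygenic scores against a control group
#'
#' `std_score = (raw - mean(controls)) / sd(controls)` with the n-1 sample
#' SD, so the control set has mean 0 and SD 1 afterwards.
#'
#' @param scores data.frame with `sample_id` and `raw_score`
#' @param control_ids sample ids forming the reference group
#' @return input data.frame with an added `std_score` column
#' @export
pgs_standardize <- function(scores, control_ids) {
  ctl <- scores$raw_score[scores$sample_id %in% control_ids]
  assert_that(length(ctl) >= 2L, "need >= 2 controls")
  s <- stats::sd(ctl)
  assert_that(s > 0, "control scores have zero variance")
  scores$std_score <- (scores$raw_score - mean(ctl)) / s
  scores
}

#' Two-sample Z-test for a group difference in mean PGS
#'
#' Unpooled (Welch-style) Z statistic
#' `z = (mean_A - mean_B) / sqrt(var_A/n_A + var_B/n_B)` with a standard
#' normal two-sided p value.
#'
#' @param group_a,group_b numeric vectors of standardized scores
#' @return list with `z`, `p`, `mean_diff`, `n_a`, `n_b`
#' @export
pgs_group_test <- function(group_a, group_b) {
  assert_that(length(group_a) >= 2L && length(group_b) >= 2L,
              "both groups need >= 2 observations")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  assert_that(va > 0 || vb > 0, "degenerate groups: zero variance")
  se <- sqrt(va / length(group_a) + vb / length(group_b))
  z <- (mean(group_a) - mean(group_b)) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       mean_diff = mean(group_a) - mean(group_b),
       n_a = length(group_a), n_b = length(group_b))
}

#' Polygenic transmission disequilibrium test (pTDT)
#'
#' For each trio the deviation is the child's score minus the mid-parental
#' mean, scaled by the standard deviation of mid-parental scores across
#' trios; under the null of no preferential transmission the deviations
#' have mean zero, tested with a one-sample t-test.
#'
#' @param child,mother,father numeric vectors of standardized scores, one
#'   entry per trio
#' @return list with `deviations`, `mean_deviation`, `t`, `df`, `p`
#' @export
pgs_ptdt <- function(child, mother, father) {
  assert_that(length(child) >= 2L &&
                length(child) == length(mother) &&
                length(child) == length(father),
              "need >= 2 trios with matched child/mother/father scores")
  midparent <- (mother + father) / 2
  s <- stats::sd(midparent)
  assert_that(s > 0, "all mid-parental scores are equal")
  dev <- (child - midparent) / s
  if (stats::sd(dev) == 0) {
    # every child sits exactly at (or a constant offset from) its midparent
    t <- if (mean(dev) == 0) 0 else sign(mean(dev)) * Inf
    return(list(deviations = dev, mean_deviation = mean(dev), t = t,
                df = length(dev) - 1L, p = if (t == 0) 1 else 0))
  }
  tt <- stats::t.test(dev, mu = 0)
  list(deviations = dev, mean_deviation = mean(dev),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Spouse-pair PGS correlation (assortative mating check)
#'
#' @param mother,father numeric score vectors, one entry per spouse pair
#' @return list with `r`, `p`, `n`
#' @export
spouse_correlation <- function(mother, father) {
  assert_that(length(mother) >= 3L && length(mother) == length(father),
              "need >= 3 matched spouse pairs")
  assert_that(stats::sd(mother) > 0 && stats::sd(father) > 0,
              "degenerate input: zero variance")
  ct <- stats::cor.test(mother, father)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(mother))
}

#' Residualize a phenotype on covariates with backwards stepwise selection
#'
#' Fits `phenotype ~ age + sex + PCs`, then repeatedly drops the eliminable
#' covariate (any PC; age and sex are always retained) with the largest
#' coefficient p-value above `p_keep`, refitting until every retained PC has
#' `p <= p_keep`. Residuals from the final fit are standardized to mean 0,
#' SD 1.
#'
#' @param phenotype numeric vector
#' @param covariates data.frame of covariates; columns named in
#'   `always_keep` are never dropped
#' @param p_keep elimination threshold (default 0.05)
#' @param always_keep covariate names never eliminated (default
#'   `c("age", "sex")`, intersected with available columns)
#' @return list with `residuals` (standardized), `retained` (covariate
#'   names) and `fit` (the final `lm`)
#' @export
residualize_phenotype <- function(phenotype, covariates, p_keep = 0.05,
                                  always_keep = c("age", "sex")) {
  assert_that(stats::sd(phenotype) > 0, "phenotype has zero variance")
  covariates <- as.data.frame(covariates)
  assert_that(length(phenotype) > ncol(covariates) + 2L,
              "too few observations for the covariate set")
  always_keep <- intersect(always_keep, names(covariates))
  vars <- names(covariates)
  repeat {
    d <- cbind(data.frame(.y = phenotype), covariates[vars])
    fit <- stats::lm(.y ~ ., data = d)
    assert_that(!any(is.na(stats::coef(fit))),
                "rank-deficient design; collinear covariates: ",
                paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
    p <- summary(fit)$coefficients[, 4]
    p <- p[setdiff(names(p), "(Intercept)")]
    droppable <- setdiff(vars, always_keep)
    p <- p[names(p) %in% droppable]
    if (!length(p) || max(p) <= p_keep) break
    vars <- setdiff(vars, names(which.max(p)))
  }
  r <- stats::residuals(fit)
  list(residuals = as.numeric(scale(r)), retained = vars, fit = fit)
}

#' PGS prediction: correlation and incremental variance explained
#'
#' Pearson correlation between a (residualized) phenotype and the PGS, with
#' a two-sided p-value. When `covariates` are supplied the incremental-R2
#' analysis runs on the unresidualized scale: `baseline_r2` is the adjusted
#' R2 of the covariate-only model, `delta_r2` the increase in unadjusted R2
#' from adding the PGS term (`delta_r2_adj` the adjusted-scale analogue),
#' and `pct_change = 100 * delta_r2_adj / baseline_r2`, matching the
#' "percent increase over the baseline model" convention of adjusted-R2
#' reports.
#'
#' @param response numeric phenotype (or residual) vector
#' @param pgs numeric vector of standardized scores
#' @param covariates optional data.frame of covariates for the incremental
#'   model
#' @return list with `r`, `p`, `n`, and (with covariates) `baseline_r2`,
#'   `delta_r2`, `delta_r2_adj`, `pct_change`, `beta_pgs`, `p_pgs`
#' @export
pgs_predict <- function(response, pgs, covariates = NULL) {
  assert_that(length(response) == length(pgs), "length mismatch")
  assert_that(length(response) >= 10L, "need n >= 10")
  ct <- stats::cor.test(response, pgs)
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = length(response))
  if (!is.null(covariates)) {
    d0 <- cbind(data.frame(.y = response), as.data.frame(covariates))
    base <- stats::lm(.y ~ ., data = d0)
    full <- stats::lm(.y ~ ., data = cbind(d0, .pgs = pgs))
    sb <- summary(base); sf <- summary(full)
    out$baseline_r2 <- sb$adj.r.squared
    out$delta_r2 <- sf$r.squared - sb$r.squared
    out$delta_r2_adj <- sf$adj.r.squared - sb$adj.r.squared
    out$pct_change <- 100 * out$delta_r2_adj / out$baseline_r2
    cf <- sf$coefficients[".pgs", ]
    out$beta_pgs <- unname(cf[1]); out$p_pgs <- unname(cf[4])
  }
  out
}

#' Bonferroni significance flags
#'
#' Flags `p <= family_alpha / m` (inclusive).
#'
#' @param p_values numeric vector in \[0, 1\]
#' @param m number of tests (default 50)
#' @param family_alpha family-wise level (default 0.05)
#' @return list with `threshold` and logical `significant`
#' @export
bonferroni_flags <- function(p_values, m = 50L, family_alpha = 0.05) {
  assert_that(all(p_values >= 0 & p_values <= 1), "p values must be in [0,1]")
  thr <- family_alpha / m
  list(threshold = thr, significant = p_values <= thr)
}

#' Analytic power for the study's two test designs
#'
#' `design = "two_sample_mean"`: two-sided normal-approximation power for a
#' standardized mean difference `effect` (SD units) between groups of sizes
#' `n1` and `n2`; the noncentrality is `effect / sqrt(1/n1 + 1/n2)`.
#' `design = "r2_one_predictor"`: power of the overall F-test of a
#' one-predictor linear regression explaining `effect` = R2 of the variance
#' at sample size `n`, via the noncentral F with `df1 = 1`, `df2 = n - 2`
#' and noncentrality `n * R2 / (1 - R2)`.
#'
#' @param design `"two_sample_mean"` or `"r2_one_predictor"`
#' @param effect standardized mean difference, or R2 fraction
#' @param n1,n2 group sizes (two-sample design)
#' @param n total sample size (R2 design)
#' @param alpha two-sided significance level (default 0.05)
#' @return power as a fraction in \[0, 1\]
#' @export
pgs_power <- function(design = c("two_sample_mean", "r2_one_predictor"),
                      effect, n1 = NULL, n2 = NULL, n = NULL, alpha = 0.05) {
  design <- match.arg(design)
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(effect >= 0, "effect must be non-negative")
  if (design == "two_sample_mean") {
    assert_that(!is.null(n1) && !is.null(n2), "two_sample_mean needs n1 and n2")
    se <- sqrt(1 / n1 + 1 / n2)
    zc <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(effect / se - zc) + stats::pnorm(-effect / se - zc)
  } else {
    assert_that(!is.null(n) && n > 2, "r2_one_predictor needs n > 2")
    assert_that(effect < 1, "R2 must be < 1")
    ncp <- n * effect / (1 - effect)
    crit <- stats::qf(1 - alpha, 1, n - 2)
    stats::pf(crit, 1, n - 2, ncp = ncp, lower.tail = FALSE)
  }
}
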