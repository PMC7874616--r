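# scoring and standardization -----------------------------------------

test_that("scoring is the dosage-weight dot product", {
  dos <- matrix(c(2, 1), 1, 2, dimnames = list("S1", c("v1", "v2")))
  w <- data.frame(variant = c("v1", "v2"), effect_allele = c("A", "G"),
                  effect = c(0.5, -0.2))
  expect_equal(pgs_score(dos, w)$raw_score, 0.8)
  expect_equal(pgs_score(dos * 0, w)$raw_score, 0)
})

test_that("scoring matches a naive per-sample loop on a random panel", {
  set.seed(2)
  dos <- matrix(sample(0:2, 100 * 50, TRUE), 100, 50,
                dimnames = list(sprintf("S%03d", 1:100),
                                sprintf("v%02d", 1:50)))
  w <- data.frame(variant = colnames(dos), effect_allele = "A",
                  effect = rnorm(50))
  got <- pgs_score(dos, w)$raw_score
  oracle <- vapply(seq_len(nrow(dos)), function(i) {
    s <- 0
    for (j in seq_len(nrow(w))) s <- s + dos[i, w$variant[j]] * w$effect[j]
    s
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("missing dosages impute to twice the effect-allele frequency", {
  dos <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2,
                dimnames = list(c("a", "b", "c"), c("v1", "v2")))
  w <- data.frame(variant = c("v1", "v2"), effect_allele = "A", effect = c(1, 0))
  got <- pgs_score(dos, w)
  expect_equal(got$raw_score[3], 1)  # mean of 0 and 2
  expect_equal(pgs_score(dos, w, missing = "skip")$raw_score[3], 0)
  w2 <- rbind(w, data.frame(variant = "v99", effect_allele = "A", effect = 5))
  expect_warning(pgs_score(dos, w2), "absent")
  expect_error(suppressWarnings(
    pgs_score(dos, w2[3, , drop = FALSE])), "no usable")
})

test_that("standardization gives controls mean 0 and SD 1", {
  sc <- data.frame(sample_id = c("c1", "c2", "t1", "t2"),
                   raw_score = c(0, 2, 1, 2))
  std <- pgs_standardize(sc, c("c1", "c2"))
  expect_equal(std$std_score[3], 0)
  expect_equal(std$std_score[4], 1 / sqrt(2))
  ctl <- std$std_score[1:2]
  expect_equal(mean(ctl), 0)
  expect_equal(sd(ctl), 1)
  # invariance under adding a constant to all raw scores
  sc2 <- sc; sc2$raw_score <- sc2$raw_score + 17
  expect_equal(pgs_standardize(sc2, c("c1", "c2"))$std_score, std$std_score)
  sc3 <- sc; sc3$raw_score <- rep(1, 4)
  expect_error(pgs_standardize(sc3, c("c1", "c2")), "zero variance")
})

# group test and pTDT --------------------------------------------------

test_that("identical groups give z = 0, p = 1", {
  g <- c(-1, 0, 1, 2)
  res <- pgs_group_test(g, g)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  expect_error(pgs_group_test(c(1, 1), c(1, 1)), "zero variance")
})

test_that("pTDT deviations are midparent-SD scaled and location invariant", {
  set.seed(4)
  mo <- rnorm(50); fa <- rnorm(50)
  child <- (mo + fa) / 2
  null <- pgs_ptdt(child, mo, fa)
  expect_equal(null$t, 0)
  expect_equal(null$p, 1)
  expect_true(all(null$deviations == 0))
  # adding a constant to every score leaves deviations unchanged
  child2 <- rnorm(50)
  base <- pgs_ptdt(child2, mo, fa)
  shifted <- pgs_ptdt(child2 + 3, mo + 3, fa + 3)
  expect_equal(shifted$deviations, base$deviations)
  expect_error(pgs_ptdt(c(1, 2), c(1, 1), c(1, 1)), "equal")
})

test_that("planted over-transmission of 0.2 midparent-SD is recovered", {
  set.seed(6)
  n <- 500
  mo <- rnorm(n); fa <- rnorm(n)
  mid <- (mo + fa) / 2
  child <- mid + 0.2 * sd(mid) + rnorm(n, 0, 0.5)
  res <- pgs_ptdt(child, mo, fa)
  se <- sd(res$deviations) / sqrt(n)
  expect_lt(abs(res$mean_deviation - 0.2), 3 * se)
  expect_lt(res$p, 0.05)
})

test_that("spouse correlation hits the exact and null benchmarks", {
  x <- rnorm(20)
  expect_equal(spouse_correlation(x, x)$r, 1)
  expect_equal(spouse_correlation(x, -x)$r, -1)
  set.seed(10)
  null <- spouse_correlation(rnorm(324), rnorm(324))
  expect_lt(abs(null$r), 3 / sqrt(324))
  expect_error(spouse_correlation(rep(1, 10), rnorm(10)), "zero variance")
})

# residualization and prediction ---------------------------------------

test_that("backwards stepwise retains planted PCs and drops noise PCs", {
  set.seed(14)
  n <- 400
  cov <- data.frame(age = runif(n, 2, 17), sex = rbinom(n, 1, 0.5))
  for (k in 1:10) cov[[paste0("pc", k)]] <- rnorm(n)
  y <- 2 * cov$pc3 + rnorm(n)
  res <- residualize_phenotype(y, cov)
  expect_true("pc3" %in% res$retained)
  expect_true(all(c("age", "sex") %in% res$retained))
  expect_equal(mean(res$residuals), 0, tolerance = 1e-10)
  expect_equal(sd(res$residuals), 1)
  # phenotype independent of all PCs: most PCs eliminated
  y2 <- rnorm(n)
  res2 <- residualize_phenotype(y2, cov)
  expect_lt(length(setdiff(res2$retained, c("age", "sex"))), 4)
  expect_error(residualize_phenotype(rep(1, n), cov), "zero variance")
})

test_that("prediction returns r, p and incremental R2", {
  set.seed(15)
  n <- 1000
  pgs <- rnorm(n)
  cov <- data.frame(age = runif(n), sex = rbinom(n, 1, 0.5))
  # exact case: residuals equal the PGS
  exact <- pgs_predict(pgs, pgs)
  expect_equal(exact$r, 1)
  # null case: r near 0, delta R2 near 0
  y0 <- 0.5 * cov$age + rnorm(n)
  null <- pgs_predict(y0, pgs, covariates = cov)
  expect_lt(abs(null$r), 3 / sqrt(n))
  expect_lt(null$delta_r2, 0.01)
  expect_gte(null$delta_r2, 0)
  expect_error(pgs_predict(rnorm(5), rnorm(6)), "length mismatch")
})

test_that("planted incremental R2 is recovered without bias", {
  set.seed(16)
  n <- 1222; reps <- 60
  deltas <- replicate(reps, {
    pgs <- rnorm(n)
    cov <- data.frame(age = runif(n), sex = rbinom(n, 1, 0.5))
    y <- 0.3 * cov$age + sqrt(0.04) * pgs + sqrt(0.96) * rnorm(n)
    pgs_predict(y, pgs, covariates = cov)$delta_r2
  })
  se <- sd(deltas) / sqrt(reps)
  expect_lt(abs(mean(deltas) - 0.04), 3 * se + 0.002)
})

# multiple testing and power -------------------------------------------

test_that("Bonferroni flags use an inclusive threshold", {
  res <- bonferroni_flags(c(1e-3, 1.1e-3, 0.04), m = 50)
  expect_equal(res$threshold, 1e-3)
  expect_equal(res$significant, c(TRUE, FALSE, FALSE))
  expect_true(bonferroni_flags(0.05, m = 1)$significant)
  expect_error(bonferroni_flags(1.5), "\\[0,1\\]")
})

test_that("power equals alpha at zero effect and is monotone", {
  for (a in c(0.001, 0.05))
    expect_equal(pgs_power("two_sample_mean", effect = 0, n1 = 100, n2 = 100,
                           alpha = a), a, tolerance = 1e-12)
  p1 <- pgs_power("two_sample_mean", effect = 0.2, n1 = 100, n2 = 100)
  p2 <- pgs_power("two_sample_mean", effect = 0.3, n1 = 100, n2 = 100)
  p3 <- pgs_power("two_sample_mean", effect = 0.2, n1 = 400, n2 = 400)
  expect_gt(p2, p1); expect_gt(p3, p1)
  q1 <- pgs_power("r2_one_predictor", effect = 0.014, n = 500, alpha = 1e-3)
  q2 <- pgs_power("r2_one_predictor", effect = 0.014, n = 1222, alpha = 1e-3)
  expect_gt(q2, q1)
  expect_error(pgs_power("two_sample_mean", effect = 0.1, n1 = 10, n2 = 10,
                         alpha = 2), "alpha")
})
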