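#' Classify a pairwise relationship from IBD statistics
#'
#' Threshold rules on the genome-wide identity-by-descent summary
#' (`PI_HAT = Z2 + Z1/2`, with `Zk = P(IBD = k)`), evaluated in precedence
#' order so every valid input receives exactly one label:
#'
#' 1. monozygotic: `PI_HAT > 0.8` and `Z2 > 0.8`;
#' 2. parent-offspring: `PI_HAT > 0.45`, `Z1 > 0.8`, `Z2 < 0.1`;
#' 3. full sibling: `PI_HAT > 0.35`, `0.3 < Z1 < 0.8`, `Z2 > 0.1`;
#' 4. half sibling / 2nd degree: `PI_HAT > 0.1`, `Z1 > 0.45`, `Z2 < 0.1`;
#' 5. otherwise unrelated/unclassified.
#'
#' Inputs violating `Z0+Z1+Z2 = 1` or `PI_HAT = Z1/2 + Z2` (tolerance 0.01)
#' raise a validation error rather than silently misclassifying.
#'
#' @param pair list or one-row data.frame with `PI_HAT`, `Z0`, `Z1`, `Z2`
#' @return one of `"monozygotic"`, `"parent_offspring"`, `"full_sibling"`,
#'   `"half_sibling_or_2nd_degree"`, `"unrelated_or_unclassified"`
#' @export
classify_relationship <- function(pair) {
  with(pair, {
    assert_that(abs(Z0 + Z1 + Z2 - 1) <= 0.01,
                "invalid PairIBD: Z0+Z1+Z2 must be 1 (+/- 0.01)")
    assert_that(abs(PI_HAT - (0.5 * Z1 + Z2)) <= 0.01,
                "invalid PairIBD: PI_HAT must equal Z1/2 + Z2 (+/- 0.01)")
    if (PI_HAT > 0.8 && Z2 > 0.8) "monozygotic"
    else if (PI_HAT > 0.45 && Z1 > 0.8 && Z2 < 0.1) "parent_offspring"
    else if (PI_HAT > 0.35 && Z1 > 0.3 && Z1 < 0.8 && Z2 > 0.1) "full_sibling"
    else if (PI_HAT > 0.1 && Z1 > 0.45 && Z2 < 0.1) "half_sibling_or_2nd_degree"
    else "unrelated_or_unclassified"
  })
}

#' Sex check from X-chromosome inbreeding with consanguinity rescue
#'
#' Genetic sex is called female when the X-chromosome inbreeding coefficient
#' `x_inbreeding_F < female_max_F`, male when `> male_min_F`, and
#' inconclusive in between. Reported females in the inconclusive band are
#' rescued (kept as female) when their genome-wide inbreeding coefficient is
#' at least `rescue_genome_F` — an elevated X-chromosome F consistent with
#' consanguineous ancestry rather than a sample mix-up. Clear conflicts
#' between genetic and reported sex are mismatches; anything else in the
#' band is excluded as inconclusive.
#'
#' @param record list or one-row data.frame with `reported_sex`
#'   (`"male"`/`"female"`/`"unknown"`), `x_inbreeding_F`, `genome_F`
#' @param female_max_F,male_min_F band limits (defaults 0.25 and 0.75)
#' @param rescue_genome_F genome-wide F needed for the rescue (default 0.05)
#' @return one of `"consistent"`, `"rescued_female"`, `"mismatch"`,
#'   `"inconclusive_excluded"`
#' @export
sex_check <- function(record, female_max_F = 0.25, male_min_F = 0.75,
                      rescue_genome_F = 0.05) {
  xf <- record$x_inbreeding_F
  genetic <- if (xf < female_max_F) "female"
             else if (xf > male_min_F) "male"
             else "inconclusive"
  reported <- record$reported_sex
  if (genetic != "inconclusive") {
    if (reported == "unknown" || reported == genetic) return("consistent")
    return("mismatch")
  }
  if (reported == "female" &&
      (record$genome_F %||% NA_real_) >= rescue_genome_F &&
      !is.na(record$genome_F))
    return("rescued_female")
  "inconclusive_excluded"
}

#' Trio Mendelian error rate
#'
#' Counts variants where the child's biallelic genotype (0/1/2 dosage of an
#' arbitrary allele) is impossible given the parents' genotypes — e.g.
#' parents 0 x 0 force child 0, parents 0 x 2 force child 1 — and divides
#' by the number of variants where all three genotypes are non-missing.
#'
#' @param child,father,mother numeric vectors of genotypes in \{0, 1, 2\},
#'   `NA` for missing, one entry per variant
#' @return list with `errors`, `tested` and `rate`
#' @export
mendelian_error_rate <- function(child, father, mother) {
  assert_that(length(child) > 0L, "empty variant panel")
  assert_that(length(child) == length(father) && length(child) == length(mother),
              "genotype vectors must have equal length")
  ok <- !is.na(child) & !is.na(father) & !is.na(mother)
  assert_that(any(ok), "no variant with complete trio genotypes")
  c0 <- child[ok]; f0 <- father[ok]; m0 <- mother[ok]
  # transmissible allele counts: parent 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  lo <- function(g) ifelse(g == 2, 1, 0)   # minimum transmitted
  hi <- function(g) ifelse(g == 0, 0, 1)   # maximum transmitted
  bad <- c0 < lo(f0) + lo(m0) | c0 > hi(f0) + hi(m0)
  list(errors = sum(bad), tested = sum(ok), rate = sum(bad) / sum(ok))
}

#' Assign ancestry from projected principal components
#'
#' A population is a candidate when every coordinate of the individual lies
#' within `n_sd` standard deviations of that population's mean on the
#' corresponding PC. One candidate gives that label; none gives `"other"`;
#' several are resolved to the nearest population in SD-scaled Euclidean
#' distance, flagged ambiguous.
#'
#' @param coords numeric vector of projected PC coordinates
#' @param populations named list; each element a list with numeric `mean`
#'   and `sd` vectors of the same length as `coords`
#' @param n_sd the SD radius (default 4)
#' @return list with `label` and `ambiguous` (logical)
#' @export
assign_ancestry <- function(coords, populations, n_sd = 4) {
  assert_that(length(populations) > 0L, "populations must be non-empty")
  for (p in populations)
    assert_that(length(p$mean) == length(coords) &&
                  length(p$sd) == length(coords),
                "population mean/sd dimension mismatch with coords")
  inside <- vapply(populations, function(p)
    all(abs(coords - p$mean) <= n_sd * p$sd), logical(1))
  cand <- names(populations)[inside]
  if (length(cand) == 0L) return(list(label = "other", ambiguous = FALSE))
  if (length(cand) == 1L) return(list(label = cand, ambiguous = FALSE))
  d <- vapply(populations[cand], function(p)
    sqrt(sum(((coords - p$mean) / p$sd)^2)), numeric(1))
  list(label = cand[which.min(d)], ambiguous = TRUE)
}

#' Nearest-neighbour control matching on principal components
#'
#' For each case, takes the `k` pool members with least Euclidean distance
#' on the first `n_pcs` coordinates. The default mode is greedy without
#' replacement in ascending case-identifier order (each case removes its
#' matches from the pool); with `replace = TRUE` every case sees the full
#' pool. Distance ties break by pool identifier.
#'
#' @param cases named matrix/data.frame of case PC coordinates (rownames =
#'   case ids)
#' @param pool named matrix/data.frame of pool PC coordinates (rownames =
#'   pool ids)
#' @param k controls per case (default 5)
#' @param n_pcs number of leading PCs used (default 3)
#' @param replace match with replacement (default FALSE)
#' @return named list mapping case id to a character vector of `k` pool ids
#' @export
match_controls <- function(cases, pool, k = 5L, n_pcs = 3L, replace = FALSE) {
  cases <- as.matrix(cases); pool <- as.matrix(pool)
  assert_that(ncol(cases) >= n_pcs && ncol(pool) >= n_pcs,
              "fewer coordinates than n_pcs")
  if (!replace)
    assert_that(nrow(pool) >= k * nrow(cases),
                "pool too small for without-replacement matching")
  cases <- cases[order(rownames(cases)), , drop = FALSE]
  remaining <- rep(TRUE, nrow(pool))
  out <- list()
  for (i in seq_len(nrow(cases))) {
    idx <- which(remaining)
    d <- sqrt(colSums((t(pool[idx, seq_len(n_pcs), drop = FALSE]) -
                         cases[i, seq_len(n_pcs)])^2))
    ord <- idx[order(d, rownames(pool)[idx])]
    pick <- ord[seq_len(k)]
    out[[rownames(cases)[i]]] <- rownames(pool)[pick]
    if (!replace) remaining[pick] <- FALSE
  }
  out
}

#' Method-of-moments IBD estimation from a biallelic dosage panel
#'
#' PLINK-style moment estimator: observed identity-by-state (IBS) counts are
#' combined with their allele-frequency expectations under IBD states 0/1/2
#' to estimate `Z0`, `Z1`, `Z2` (clamped to \[0,1\] and renormalized) and
#' `PI_HAT = Z2 + Z1/2`. Intended for the synthetic cohort generator's
#' genotype-derived IBD path; real studies should use dedicated tooling.
#'
#' @param g1,g2 numeric genotype vectors in \{0, 1, 2\} (`NA` allowed)
#' @param freq effect/reference allele frequencies per variant (computed
#'   from the two samples' cohort if omitted — pass cohort-level
#'   frequencies for stable estimates)
#' @return list with `Z0`, `Z1`, `Z2`, `PI_HAT`
#' @export
estimate_ibd <- function(g1, g2, freq) {
  ok <- !is.na(g1) & !is.na(g2) & freq > 0 & freq < 1
  g1 <- g1[ok]; g2 <- g2[ok]; p <- freq[ok]; q <- 1 - p
  ibs <- ifelse(abs(g1 - g2) == 2, 0, ifelse(g1 == g2, 2, 1))
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e1_ibd1 <- sum(2 * p * q)
  i0 <- sum(ibs == 0); i1 <- sum(ibs == 1)
  z0 <- i0 / e0_ibd0
  z1 <- (i1 - z0 * e1_ibd0) / e1_ibd1
  z2 <- 1 - z0 - z1
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  list(Z0 = z[1], Z1 = z[2], Z2 = z[3], PI_HAT = z[3] + z[2] / 2)
}
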