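# sample_qc ------------------------------------------------------------

test_that("a sample far from the batch mean fails the intensity rule", {
  set.seed(1)
  n <- 40
  stats <- data.frame(sample_id = sprintf("S%02d", 1:n),
                      LRRSD = rnorm(n, 0.12, 0.01),
                      BAFSD = rnorm(n, 0.04, 0.005),
                      GCWF = rnorm(n, 0, 0.01))
  # plant an LRRSD outlier well beyond 3 batch SDs
  stats$LRRSD[1] <- mean(stats$LRRSD[-1]) + 8 * sd(stats$LRRSD[-1])
  res <- sample_qc(stats)
  expect_false(res$pass[1])
  expect_match(res$reasons[1], "LRRSD")
  expect_true(all(res$pass[-1]))
})

test_that("CNVs covering >20% of a chromosome fail the aneuploidy rule", {
  stats <- data.frame(sample_id = c("A", "B", "C"),
                      LRRSD = c(0.1, 0.1, 0.1), BAFSD = c(0.04, 0.04, 0.04),
                      GCWF = c(0, 0, 0))
  fr <- data.frame(sample_id = c("A", "B"), chrom = "chr1",
                   fraction = c(0.25, 0.19))
  res <- sample_qc(stats, cnv_fractions = fr)
  expect_equal(res$reasons, c("aneuploidy", "", ""))
})

test_that("identical statistics all pass (degenerate zero SD)", {
  stats <- data.frame(sample_id = c("A", "B", "C"),
                      LRRSD = 0.1, BAFSD = 0.04, GCWF = 0)
  expect_true(all(sample_qc(stats)$pass))
  expect_error(sample_qc(stats[1, , drop = FALSE]), ">= 2 samples")
})

# build_common_mask ----------------------------------------------------

test_that("the common mask is exactly the region reaching the support threshold", {
  base <- make_call("chr3", 1000000, 1050000)
  stack <- do.call(rbind, lapply(1:30, function(i) {
    x <- base; x$sample_id <- sprintf("S%02d", i); x
  }))
  m <- build_common_mask(stack, min_support = 25L)
  expect_equal(m, data.frame(chrom = "chr3", start = 1000000L,
                             end = 1050000L), ignore_attr = TRUE)
  expect_equal(nrow(build_common_mask(stack[1:24, ], min_support = 25L)), 0L)
})

test_that("staircase coverage masks match the per-base oracle", {
  set.seed(7)
  for (rep in 1:10) {
    calls <- random_calls(40, max_pos = 20000, max_len = 6000)
    for (support in c(3L, 8L)) {
      m <- build_common_mask(calls, min_support = support)
      o <- oracle_mask(calls, support, limit = 30000L)
      if (is.null(o)) expect_equal(nrow(m), 0L)
      else expect_equal(m[order(m$chrom, m$start), ],
                        o[order(o$chrom, o$start), ], ignore_attr = TRUE)
    }
  }
})

# filter_cnvs ----------------------------------------------------------

filter_resources <- function() {
  list(centromeres = data.frame(chrom = "chr1", start = 24000001L,
                                end = 26000000L),
       mhc = data.frame(chrom = "chr2", start = 28477797L, end = 33448354L),
       segdups = data.frame(chrom = "chr1", start = 40000001L,
                            end = 40200000L),
       benign = data.frame(chrom = "chr3", start = 1000001L, end = 1100000L),
       exons = data.frame(chrom = rep(c("chr1", "chr2", "chr3"), each = 2),
                          start = c(1e6, 5e6, 1e6, 5e6, 1e6, 5e6) + 1,
                          end = c(1e6, 5e6, 1e6, 5e6, 1e6, 5e6) + 5000))
}

test_that("the cascade removes at the first failing rule in order", {
  res <- filter_resources()
  calls <- rbind(
    make_call("chr1", 1000001, 1040000, confidence = 9.9),     # confidence
    make_call("chr1", 25999999, 26100000),                     # centromere 2 bp
    make_call("chr2", 33448354, 33600000),                     # MHC by 1 bp
    make_call("chr1", 40000001, 40150000),                     # segdup 75%
    make_call("chr1", 1000001, 1020000, n_snps = 12L),         # retained: 20 kb
    make_call("chr1", 1000001, 1019999, n_snps = 12L),         # < 20 kb
    make_call("chr1", 1000001, 1040000, n_snps = 9L),          # < 10 SNPs
    make_call("chr3", 1020001, 1100000),                       # benign 100%
    make_call("chr1", 10000001, 10040000))                     # non-exonic
  aud <- filter_cnvs(calls, resources = res)
  expect_equal(aud$failed_filter,
               c("confidence", "centromere", "mhc", "segdup", NA, "size",
                 "size", "benign", "noncoding"))
  expect_equal(aud$status == "retained", is.na(aud$failed_filter))
})

test_that("a CNV with exactly 20 kb and 10+ SNPs passes the size rule", {
  calls <- make_call("chr1", 1000001, 1020000, n_snps = 10L)
  aud <- filter_cnvs(calls, resources = filter_resources())
  expect_equal(aud$status, "retained")
})

test_that("internal common mask removes calls overlapping it by >= 50%", {
  mask <- data.frame(chrom = "chr1", start = 1000001L, end = 1100000L)
  inside <- make_call("chr1", 1040001, 1080000)   # fully in the mask
  graze <- make_call("chr1", 1090001, 1200000)    # < 50% in the mask
  aud <- filter_cnvs(rbind(inside, graze), resources = list(), mask = mask)
  expect_equal(aud$failed_filter, c("common_internal", NA))
})

test_that("gnomAD and external-common rules use reciprocal matching", {
  res <- list(
    common_external = data.frame(chrom = "chr1", start = 1000001L,
                                 end = 1100000L),
    gnomad = data.frame(chrom = "chr2", start = 1000001L, end = 1100000L,
                        max_freq = c(0.05)))
  hit_ext <- make_call("chr1", 1010001, 1090000)     # reciprocal 80%
  small <- make_call("chr1", 1000001, 1020000)       # only 20% of the entry
  hit_gno <- make_call("chr2", 1000001, 1100000)
  aud <- filter_cnvs(rbind(hit_ext, small, hit_gno), resources = res)
  expect_equal(aud$failed_filter, c("common_external", NA, "gnomad"))
  # a rare gnomAD entry (< 1%) never removes
  res$gnomad$max_freq <- 0.005
  aud2 <- filter_cnvs(hit_gno, resources = res)
  expect_equal(aud2$status, "retained")
})

test_that("conservation and order-independence hold", {
  set.seed(11)
  res <- filter_resources()
  calls <- random_calls(40, chroms = c("chr1", "chr2", "chr3"),
                        max_pos = 45000000, max_len = 300000)
  aud <- filter_cnvs(calls, resources = res)
  expect_equal(sum(aud$status == "retained") + sum(aud$status == "removed"),
               nrow(calls))
  perm <- sample(nrow(calls))
  aud2 <- filter_cnvs(calls[perm, ], resources = res)
  expect_equal(aud2$failed_filter, aud$failed_filter[perm])
})

test_that("removing a resource region never increases that rule's removals", {
  set.seed(12)
  res <- filter_resources()
  res$segdups <- rbind(res$segdups,
                       data.frame(chrom = "chr2", start = 10000001L,
                                  end = 10500000L))
  calls <- random_calls(60, chroms = c("chr1", "chr2"),
                        max_pos = 45000000, max_len = 400000)
  n_before <- sum(filter_cnvs(calls, res)$failed_filter == "segdup",
                  na.rm = TRUE)
  res$segdups <- res$segdups[1, , drop = FALSE]
  n_after <- sum(filter_cnvs(calls, res)$failed_filter == "segdup",
                 na.rm = TRUE)
  expect_lte(n_after, n_before)
})

test_that("naming a rule without its resource is a configuration error", {
  expect_error(filter_cnvs(make_call("chr1", 1, 100), resources = list(),
                           rules = c("confidence", "segdup")),
               "segdup")
})

test_that("genes resource separates noncoding from nongenic", {
  res <- list(exons = data.frame(chrom = "chr1", start = 1000001L,
                                 end = 1001000L),
              genes = data.frame(chrom = "chr1", start = 900001L,
                                 end = 1100000L))
  intronic <- make_call("chr1", 1050001, 1090000)  # in gene, misses exon
  desert <- make_call("chr1", 20000001, 20040000)  # no gene at all
  aud <- filter_cnvs(rbind(intronic, desert), resources = res)
  expect_equal(aud$failed_filter, c("noncoding", "nongenic"))
})
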