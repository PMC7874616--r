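noise_free <- function(seed = 7, ...) {
  sim_config(seed = seed, n_families = 8, n_unrelated = 4,
             fragmentation_rate = 0, boundary_jitter_bp = 0, fp_rate = 0, ...)
}

test_that("a fixed seed gives identical bundles across runs", {
  cfg <- sim_config(seed = 1, n_families = 10)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  co <- generate_cohort(cfg)
  expect_identical(generate_caller_views(co, cfg),
                   generate_caller_views(co, cfg))
  expect_identical(generate_reference_tracks(cfg, co$truth$true_cnvs),
                   generate_reference_tracks(cfg, co$truth$true_cnvs))
})

test_that("an empty cohort is a valid degenerate case", {
  cfg <- sim_config(seed = 1, n_families = 0, n_unrelated = 0, n_auto_cnvs = 0)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$pedigree), 0L)
  expect_equal(nrow(co$truth$true_cnvs), 0L)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(fragmentation_rate = 1.5), "fragmentation_rate")
  expect_error(sim_config(pgs_r2 = -0.1), "pgs_r2")
  expect_error(sim_config(n_families = -1), "n_families")
  expect_error(sim_config(n_variants = 0), "n_variants")
})

test_that("planted carriers must exist in the cohort", {
  bad <- data.frame(carrier = "NOPE", chrom = "chr1", start = 1e6,
                    end = 2e6, type = "deletion")
  expect_error(generate_cohort(sim_config(seed = 1, cnv_truth = bad)), "NOPE")
})

test_that("group PGS shift is realized in expectation", {
  cfg <- sim_config(seed = 3, n_families = 300, n_unrelated = 200,
                    group_pgs_shifts = c(ASD = 0.3), n_variants = 50)
  co <- generate_cohort(cfg)
  asd <- co$scores$raw_score[co$pedigree$group == "ASD"]
  unr <- co$scores$raw_score[co$pedigree$group == "UNR"]
  se <- sqrt(var(asd) / length(asd) + var(unr) / length(unr))
  expect_lt(abs((mean(asd) - mean(unr)) - 0.3), 3 * se)
})

test_that("children are Mendelian-consistent with their parents", {
  cfg <- sim_config(seed = 5, n_families = 10, n_unrelated = 0)
  co <- generate_cohort(cfg)
  kids <- co$pedigree[!is.na(co$pedigree$father_id), ]
  for (i in seq_len(nrow(kids))) {
    res <- mendelian_error_rate(co$dosages[kids$sample_id[i], ],
                                co$dosages[kids$father_id[i], ],
                                co$dosages[kids$mother_id[i], ])
    expect_equal(res$errors, 0L)
  }
})

test_that("noise-free caller views equal the truth set exactly", {
  cfg <- noise_free()
  co <- generate_cohort(cfg)
  v <- generate_caller_views(co, cfg)
  cols <- c("sample_id", "chrom", "start", "end", "type")
  truth <- co$truth$true_cnvs[order(co$truth$true_cnvs$sample_id,
                                    co$truth$true_cnvs$chrom,
                                    co$truth$true_cnvs$start), cols]
  expect_equal(v$calls_a[, cols], truth, ignore_attr = TRUE)
  expect_equal(v$calls_b[, cols], truth, ignore_attr = TRUE)
})

test_that("forced fragmentation splits every view, re-merging to the true span", {
  truth <- data.frame(carrier = NA, chrom = "chr1", start = 10000001L,
                      end = 10500000L, type = "deletion")
  cfg <- sim_config(seed = 9, n_families = 2, n_unrelated = 0,
                    fragmentation_rate = 1, boundary_jitter_bp = 0,
                    fp_rate = 0, max_frag_gap_bp = 50000L,
                    cnv_truth = transform(truth, carrier = "F001_C1"))
  co <- generate_cohort(cfg)
  v <- generate_caller_views(co, cfg)
  for (calls in list(v$calls_a, v$calls_b)) {
    expect_gte(nrow(calls), 2L)
    gaps <- calls$start[-1] - calls$end[-nrow(calls)] - 1L
    expect_true(all(gaps <= 50000L))
    m <- merge_fragments(calls, trigger_count = 0L)
    expect_equal(nrow(m), 1L)
    expect_equal(m$start, 10000001L)
    expect_equal(m$end, 10500000L)
  }
})

test_that("common regions are carried at the configured frequency in both callers", {
  crs <- data.frame(chrom = "chr3", start = 1000000L, end = 1050000L,
                    freq = 0.5)
  cfg <- sim_config(seed = 11, n_families = 15, n_unrelated = 15,
                    n_auto_cnvs = 0, fragmentation_rate = 0,
                    boundary_jitter_bp = 0, fp_rate = 0,
                    common_region_specs = crs)
  co <- generate_cohort(cfg)
  v <- generate_caller_views(co, cfg)   # ~60 samples, binomial mean ~30
  carriers_a <- sort(unique(v$calls_a$sample_id))
  carriers_b <- sort(unique(v$calls_b$sample_id))
  expect_identical(carriers_a, carriers_b)
  expect_gte(length(carriers_a), 20L)
  expect_lte(length(carriers_a), 45L)
})

test_that("false positives land in one caller and vanish in consensus", {
  cfg <- sim_config(seed = 13, n_families = 6, n_unrelated = 3,
                    n_auto_cnvs = 0, fp_rate = 1.5)
  co <- generate_cohort(cfg)
  v <- generate_caller_views(co, cfg)
  expect_gt(nrow(v$calls_a) + nrow(v$calls_b), 0L)
  cons <- intersect_callers(v$calls_a, v$calls_b)
  expect_equal(nrow(cons), 0L)
})

test_that("planted intensity outliers fail sample QC", {
  cfg <- sim_config(seed = 15, n_families = 10,
                    qc_outlier_samples = "F001_FA")
  co <- generate_cohort(cfg)
  v <- generate_caller_views(co, cfg)
  qc <- sample_qc(v$intensity_qc)
  expect_false(qc$pass[qc$sample_id == "F001_FA"])
  expect_match(qc$reasons[qc$sample_id == "F001_FA"], "LRRSD")
})

test_that("the bundle round-trips through disk exactly", {
  cfg <- noise_free(seed = 17)
  co <- generate_cohort(cfg)
  tr <- generate_reference_tracks(cfg, co$truth$true_cnvs)
  v <- generate_caller_views(co, cfg)
  dir <- withr::local_tempdir()
  write_cohort_bundle(co, v, tr, dir)
  b <- read_cohort_bundle(dir)
  expect_identical(b$pedigree, co$pedigree)
  expect_identical(b$scores, co$scores)
  expect_identical(b$phenotypes, co$phenotypes)
  expect_identical(b$pcs, co$pcs)
  expect_identical(b$ibd, co$ibd)
  expect_identical(b$weights, co$weights)
  expect_identical(b$dosages, co$dosages)
  expect_identical(b$truth_cnvs, co$truth$true_cnvs)
  expect_equal(b$calls_a, v$calls_a, ignore_attr = TRUE)
  expect_equal(b$intensity_qc, v$intensity_qc, ignore_attr = TRUE)
  expect_identical(b$centromeres[, c("chrom", "start", "end")],
                   tr$centromeres)
})

test_that("the CLI simulate and cnv-consensus subcommands run end to end", {
  dir <- withr::local_tempdir()
  cnvpgs_cli(c("simulate", "--out", dir, "--seed", "21", "--families", "4",
               "--unrelated", "2"))
  expect_true(file.exists(file.path(dir, "pedigree.tsv")))
  out <- file.path(dir, "consensus.tsv")
  suppressMessages(
    cnvpgs_cli(c("cnv-consensus", "--penn", file.path(dir, "caller_a.rawcnv"),
                 "--other", file.path(dir, "caller_b.tsv"), "--out", out)))
  expect_true(file.exists(out))
  cons <- read_tsv_table(out)
  expect_true(all(c("sample_id", "chrom", "start", "end", "type") %in%
                    names(cons)))
})
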