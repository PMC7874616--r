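#' Intensity-based sample quality control
#'
#' Flags samples whose array-intensity statistics (autosomal LRRSD, BAFSD,
#' GCWF) lie more than `sd_limit` standard deviations from the batch mean
#' (single pass; the batch is the full input), samples whose CNVs cover more
#' than `aneuploidy_fraction` of any one chromosome (an aneuploidy
#' signature), and optionally samples carrying more than
#' `max_cnvs_per_sample` CNVs. When the batch SD of a statistic is zero only
#' exact-mean values pass, so an all-identical batch passes.
#'
#' @param stats data.frame with `sample_id`, `LRRSD`, `BAFSD`, `GCWF`
#' @param cnv_fractions optional data.frame with `sample_id`, `chrom`,
#'   `fraction` giving the fraction of each chromosome covered by that
#'   sample's CNVs
#' @param cnv_counts optional named integer vector of CNV counts per sample
#' @param sd_limit SD cutoff (default 3)
#' @param aneuploidy_fraction per-chromosome coverage cutoff (default 0.2)
#' @param max_cnvs_per_sample optional count cutoff (default `Inf`, disabled)
#' @return data.frame with `sample_id`, `pass` (logical) and `reasons`
#'   (comma-separated failing rules, `""` when passing)
#' @export
sample_qc <- function(stats, cnv_fractions = NULL, cnv_counts = NULL,
                      sd_limit = 3, aneuploidy_fraction = 0.2,
                      max_cnvs_per_sample = Inf) {
  assert_that(all(c("sample_id", "LRRSD", "BAFSD", "GCWF") %in% names(stats)),
              "stats must have sample_id, LRRSD, BAFSD, GCWF columns")
  assert_that(nrow(stats) >= 2L, "sample_qc needs >= 2 samples (SD undefined)")

  reasons <- rep("", nrow(stats))
  add_reason <- function(reasons, bad, label)
    ifelse(bad, ifelse(nzchar(reasons), paste0(reasons, ",", label), label),
           reasons)
  for (st in c("LRRSD", "BAFSD", "GCWF")) {
    x <- stats[[st]]
    dev <- abs(x - mean(x))
    bad <- dev > sd_limit * stats::sd(x)   # sd 0 => only exact mean passes
    reasons <- add_reason(reasons, bad, st)
  }
  if (!is.null(cnv_fractions) && nrow(cnv_fractions)) {
    assert_that(all(cnv_fractions$fraction >= 0 & cnv_fractions$fraction <= 1),
                "chromosome CNV fractions must be in [0,1]")
    worst <- tapply(cnv_fractions$fraction, cnv_fractions$sample_id, max)
    bad <- stats$sample_id %in% names(worst)[worst > aneuploidy_fraction]
    reasons <- add_reason(reasons, bad, "aneuploidy")
  }
  if (is.finite(max_cnvs_per_sample) && !is.null(cnv_counts)) {
    bad <- stats$sample_id %in%
      names(cnv_counts)[cnv_counts > max_cnvs_per_sample]
    reasons <- add_reason(reasons, bad, "cnv_count")
  }
  data.frame(sample_id = stats$sample_id, pass = !nzchar(reasons),
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Identify internally common CNV regions
#'
#' Returns the maximal genomic intervals where base-level coverage by the
#' input CNV calls (any type, any sample) reaches `min_support`. In the
#' source cohort a support of 25 corresponded to roughly 1% of the
#' population; calls overlapping these regions by at least half are later
#' excluded as common polymorphic CNVs.
#'
#' @param calls consensus CNV call data.frame across all samples
#' @param min_support minimum per-base call coverage (default 25)
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive)
#' @export
build_common_mask <- function(calls, min_support = 25L) {
  validate_calls(calls)
  if (nrow(calls) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- lapply(split(calls, calls$chrom), function(d) {
    cov <- IRanges::coverage(IRanges::IRanges(d$start, d$end))
    hi <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
    if (length(hi) == 0L) return(NULL)
    data.frame(chrom = d$chrom[1], start = IRanges::start(hi),
               end = IRanges::end(hi), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

# cascade rule names in their canonical order
filter_rule_names <- function() {
  c("confidence", "centromere", "mhc", "segdup", "common_internal",
    "size", "benign", "common_external", "gnomad", "noncoding", "nongenic")
}

#' Rule-ordered CNV exclusion cascade with audit trail
#'
#' Applies the exclusion rules in their canonical order and removes each CNV
#' at the first failing rule, recording that rule in the audit. The rules:
#'
#' 1. `confidence`: caller confidence score `< min_confidence` (default 10);
#' 2. `centromere`: any (>= 1 bp) overlap with a centromere;
#' 3. `mhc`: any overlap with the MHC region (default hg19
#'    chr6:28,477,797-33,448,354; override for other genomes);
#' 4. `segdup`: `> 0.5` of the CNV covered by segmental duplications;
#' 5. `common_internal`: `>= 0.5` of the CNV covered by the internal common
#'    mask (see [build_common_mask()]);
#' 6. `size`: fewer than `min_snps` SNPs (default 10) and/or shorter than
#'    `min_length_bp` (default 20 kb; the rule is strict `<`, a 20,000 bp
#'    CNV passes);
#' 7. `benign`: `>= 0.7` of the CNV covered by the union of benign-catalog
#'    entries;
#' 8. `common_external`: `>= 0.5` reciprocal match to an externally common
#'    CNV;
#' 9. `gnomad`: `>= 0.5` reciprocal match to a catalog CNV whose maximum
#'    population frequency is `>= 0.01`;
#' 10. `noncoding`: no (>= 1 bp) overlap with any coding exon, while
#'     overlapping a gene body (only if a `genes` resource is supplied,
#'     otherwise any exon-free CNV fails here);
#' 11. `nongenic`: no overlap with any gene body (requires `genes`).
#'
#' Rules 2-5 and 7-11 need their resource; by default a rule lacking its
#' resource is inactive, but naming it in `rules` without the resource is a
#' configuration error.
#'
#' @param calls CNV call data.frame (consensus calls)
#' @param resources named list of reference tracks, each a data.frame with
#'   `chrom`, `start`, `end` (1-based inclusive): `centromeres`, `mhc`,
#'   `segdups`, `benign`, `common_external`, `gnomad` (extra column
#'   `max_freq`), `exons`, `genes`
#' @param mask internal common mask from [build_common_mask()]
#' @param rules character vector of rules to apply, in cascade order
#'   (default: all rules whose inputs are available)
#' @param min_confidence,min_snps,min_length_bp,segdup_fraction,common_fraction,benign_fraction,gnomad_max_freq
#'   rule thresholds (defaults 10, 10, 20000, 0.5, 0.5, 0.7, 0.01)
#' @return a filter-audit data.frame: the input calls plus `status`
#'   (`"retained"`/`"removed"`) and `failed_filter` (`NA` when retained)
#' @export
filter_cnvs <- function(calls, resources = list(), mask = NULL, rules = NULL,
                        min_confidence = 10, min_snps = 10L,
                        min_length_bp = 20000L, segdup_fraction = 0.5,
                        common_fraction = 0.5, benign_fraction = 0.7,
                        gnomad_max_freq = 0.01) {
  validate_calls(calls)
  available <- c(
    confidence = TRUE,
    centromere = !is.null(resources$centromeres),
    mhc = !is.null(resources$mhc),
    segdup = !is.null(resources$segdups),
    common_internal = !is.null(mask),
    size = TRUE,
    benign = !is.null(resources$benign),
    common_external = !is.null(resources$common_external),
    gnomad = !is.null(resources$gnomad),
    noncoding = !is.null(resources$exons),
    nongenic = !is.null(resources$genes))
  if (is.null(rules)) {
    rules <- filter_rule_names()[available[filter_rule_names()]]
  } else {
    bad <- setdiff(rules, filter_rule_names())
    assert_that(length(bad) == 0L, "unknown rule(s): ", paste(bad, collapse = ", "))
    off <- rules[!available[rules]]
    if (length(off))
      stop_config("rule(s) enabled without their resource: ",
                  paste(off, collapse = ", "))
    rules <- filter_rule_names()[filter_rule_names() %in% rules]
  }

  n <- nrow(calls)
  audit <- calls
  audit$status <- rep("retained", n)
  audit$failed_filter <- rep(NA_character_, n)
  if (n == 0L) return(audit)

  len <- ivl_len(calls$start, calls$end)
  cover_frac <- function(track) {
    vapply(seq_len(n), function(i)
      track_overlap_len(calls$chrom[i], calls$start[i], calls$end[i],
                        track) / len[i], numeric(1))
  }
  recip_match <- function(track, freq_col = NULL, min_freq = NULL) {
    vapply(seq_len(n), function(i) {
      t <- track[track$chrom == calls$chrom[i], , drop = FALSE]
      if (!is.null(freq_col)) t <- t[t[[freq_col]] >= min_freq, , drop = FALSE]
      if (nrow(t) == 0L) return(FALSE)
      o <- overlap_len(calls$start[i], calls$end[i], t$start, t$end)
      any(o / len[i] >= common_fraction &
            o / ivl_len(t$start, t$end) >= common_fraction)
    }, logical(1))
  }

  fails <- function(rule) {
    switch(rule,
      confidence = !is.na(calls$confidence) & calls$confidence < min_confidence,
      centromere = cover_frac(resources$centromeres) > 0,
      mhc = cover_frac(resources$mhc) > 0,
      segdup = cover_frac(resources$segdups) > segdup_fraction,
      common_internal = cover_frac(mask) >= common_fraction,
      size = (!is.na(calls$n_snps) & calls$n_snps < min_snps) |
             len < min_length_bp,
      benign = cover_frac(resources$benign) >= benign_fraction,
      common_external = recip_match(resources$common_external),
      gnomad = recip_match(resources$gnomad, "max_freq", gnomad_max_freq),
      noncoding = if (is.null(resources$genes))
          cover_frac(resources$exons) == 0
        else cover_frac(resources$exons) == 0 & cover_frac(resources$genes) > 0,
      nongenic = cover_frac(resources$genes) == 0)
  }

  alive <- rep(TRUE, n)
  for (rule in rules) {
    bad <- alive & fails(rule)
    audit$status[bad] <- "removed"
    audit$failed_filter[bad] <- rule
    alive <- alive & !bad
  }
  audit
}
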