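#' Merge fragmented CNV calls within one sample and caller
#'
#' Array-based CNV callers often report one large event as several adjacent
#' fragments. Following the standard consensus-calling practice, merging is
#' triggered only for (chromosome, type) strata where a sample has more calls
#' than `trigger_count` — an individual with many same-type calls on one
#' chromosome is the signature of an artificially split event. Within a
#' triggered stratum, calls sorted by start are merged greedily left-to-right
#' under two gap rules applied in order, iterated to a fixpoint:
#'
#' 1. absolute rule: merge adjacent calls whose gap is `<= max_gap_bp`;
#' 2. fractional rule: merge adjacent calls whose gap is `<= gap_fraction`
#'    times the length of the longer neighbour (configurable via
#'    `neighbour`).
#'
#' Gaps are `start2 - end1 - 1` (1-based inclusive coordinates). A merged
#' call spans the outermost coordinates; `n_snps` are summed and
#' `confidence` is the maximum of the merged members.
#'
#' @param calls CNV call data.frame for a single sample and caller
#' @param max_gap_bp absolute gap threshold in bp (default 100000)
#' @param gap_fraction fractional gap threshold (default 0.25)
#' @param trigger_count merging applies only to strata with more than this
#'   many calls (default 5)
#' @param neighbour which neighbour's length the fractional rule uses:
#'   `"longer"` (default), `"shorter"`, `"left"` or `"right"`
#' @return a CNV call data.frame at merge fixpoint
#' @export
merge_fragments <- function(calls, max_gap_bp = 100000L, gap_fraction = 0.25,
                            trigger_count = 5L,
                            neighbour = c("longer", "shorter", "left", "right")) {
  neighbour <- match.arg(neighbour)
  validate_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  assert_that(length(unique(calls$sample_id)) == 1L,
              "merge_fragments expects calls from a single sample")
  if ("caller" %in% names(calls))
    assert_that(length(unique(calls$caller)) <= 1L,
                "merge_fragments expects calls from a single caller")

  strata <- split(seq_len(nrow(calls)),
                  list(calls$chrom, calls$type), drop = TRUE)
  out <- lapply(strata, function(idx) {
    d <- calls[idx, , drop = FALSE]
    if (length(idx) <= trigger_count) return(d)
    merge_stratum(d, max_gap_bp, gap_fraction, neighbour)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

# one (chromosome, type) stratum: iterate absolute pass then fractional pass
# until neither changes anything
merge_stratum <- function(d, max_gap_bp, gap_fraction, neighbour) {
  repeat {
    n0 <- nrow(d)
    d <- merge_pass(d, function(gap, len1, len2) gap <= max_gap_bp)
    d <- merge_pass(d, function(gap, len1, len2) {
      ref <- switch(neighbour,
                    longer  = pmax(len1, len2),
                    shorter = pmin(len1, len2),
                    left    = len1,
                    right   = len2)
      gap <= gap_fraction * ref
    })
    if (nrow(d) == n0) break
  }
  d
}

# single greedy left-to-right pass with one gap predicate
merge_pass <- function(d, pred) {
  d <- d[order(d$start, d$end), , drop = FALSE]
  i <- 1L
  while (i < nrow(d)) {
    gap <- d$start[i + 1L] - d$end[i] - 1L
    if (pred(gap, ivl_len(d$start[i], d$end[i]),
             ivl_len(d$start[i + 1L], d$end[i + 1L]))) {
      d$end[i] <- max(d$end[i], d$end[i + 1L])
      d$n_snps[i] <- sum(d$n_snps[i], d$n_snps[i + 1L], na.rm = TRUE)
      d$confidence[i] <- suppressWarnings(
        max(d$confidence[i], d$confidence[i + 1L], na.rm = TRUE))
      if (!is.finite(d$confidence[i])) d$confidence[i] <- NA_real_
      d <- d[-(i + 1L), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  d
}

#' Intersect two callers' CNV calls into consensus calls
#'
#' For each same-sample, same-chromosome, same-type pair of calls (a from
#' caller A, b from caller B) with intersection length `o`, the pair is a
#' consensus candidate iff `o/length(a) >= min_overlap` and
#' `o/length(b) >= min_overlap` (reciprocal rule; set
#' `reciprocal = FALSE` for the one-way variant where either fraction
#' suffices). Candidates are resolved to a best-reciprocal-partner matching:
#' pairs are ranked by descending intersection length (ties by smaller caller
#' A start, then caller B start) and accepted greedily so that each input
#' call contributes to at most one consensus call. Consensus coordinates are
#' the intersection; `n_snps` and `confidence` are taken from the caller-A
#' member; copy-number direction must match, so a deletion never pairs with
#' a duplication.
#'
#' @param calls_a,calls_b CNV call data.frames (post-merge)
#' @param min_overlap minimum overlap fraction (default 0.5)
#' @param reciprocal require the fraction on both calls (default TRUE)
#' @return consensus CNV call data.frame (`caller = "consensus"`)
#' @export
intersect_callers <- function(calls_a, calls_b, min_overlap = 0.5,
                              reciprocal = TRUE) {
  validate_calls(calls_a); validate_calls(calls_b)
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L) return(empty_calls())

  key_a <- paste(calls_a$sample_id, calls_a$chrom, calls_a$type)
  key_b <- paste(calls_b$sample_id, calls_b$chrom, calls_b$type)
  pairs <- NULL
  for (k in intersect(unique(key_a), unique(key_b))) {
    ia <- which(key_a == k); ib <- which(key_b == k)
    grid <- expand.grid(a = ia, b = ib)
    o <- overlap_len(calls_a$start[grid$a], calls_a$end[grid$a],
                     calls_b$start[grid$b], calls_b$end[grid$b])
    fa <- o / ivl_len(calls_a$start[grid$a], calls_a$end[grid$a])
    fb <- o / ivl_len(calls_b$start[grid$b], calls_b$end[grid$b])
    keep <- if (reciprocal) fa >= min_overlap & fb >= min_overlap
            else fa >= min_overlap | fb >= min_overlap
    keep <- keep & o > 0
    if (any(keep))
      pairs <- rbind(pairs, data.frame(a = grid$a[keep], b = grid$b[keep],
                                       o = o[keep]))
  }
  if (is.null(pairs)) return(empty_calls())

  pairs <- pairs[order(-pairs$o, calls_a$start[pairs$a],
                       calls_b$start[pairs$b]), , drop = FALSE]
  used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
  take <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!used_a[pairs$a[i]] && !used_b[pairs$b[i]]) {
      take[i] <- TRUE
      used_a[pairs$a[i]] <- TRUE
      used_b[pairs$b[i]] <- TRUE
    }
  }
  pairs <- pairs[take, , drop = FALSE]
  res <- data.frame(
    sample_id = calls_a$sample_id[pairs$a],
    chrom = calls_a$chrom[pairs$a],
    start = pmax(calls_a$start[pairs$a], calls_b$start[pairs$b]),
    end = pmin(calls_a$end[pairs$a], calls_b$end[pairs$b]),
    type = calls_a$type[pairs$a],
    n_snps = if ("n_snps" %in% names(calls_a)) calls_a$n_snps[pairs$a] else NA_integer_,
    confidence = if ("confidence" %in% names(calls_a)) calls_a$confidence[pairs$a] else NA_real_,
    caller = "consensus", stringsAsFactors = FALSE)
  res <- res[order(res$sample_id, res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}
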