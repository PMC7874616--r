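# Independent brute-force oracles. These deliberately avoid the package's
# interval code paths: the merge oracle is an any-order pairwise closure,
# the consensus and coverage oracles work on explicit per-base position
# sets (keep coordinates small when using them).

oracle_merge <- function(calls, max_gap = 100000, frac = 0.25, trigger = 5) {
  strata <- split(calls, list(calls$chrom, calls$type), drop = TRUE)
  out <- lapply(strata, function(d) {
    if (nrow(d) <= trigger) return(d)
    repeat {
      d <- d[order(d$start, d$end), , drop = FALSE]
      merged <- FALSE
      for (i in seq_len(nrow(d) - 1)) {
        gap <- d$start[i + 1] - d$end[i] - 1
        l1 <- d$end[i] - d$start[i] + 1
        l2 <- d$end[i + 1] - d$start[i + 1] + 1
        if (gap <= max_gap || gap <= frac * max(l1, l2)) {
          d$end[i] <- max(d$end[i], d$end[i + 1])
          d$n_snps[i] <- sum(d$n_snps[i], d$n_snps[i + 1], na.rm = TRUE)
          d$confidence[i] <- max(d$confidence[i], d$confidence[i + 1])
          d <- d[-(i + 1), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (!merged) return(d)
    }
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-base consensus oracle (same pairing policy, per-base arithmetic)
oracle_consensus <- function(a, b, min_overlap = 0.5) {
  cand <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$sample_id[i] != b$sample_id[j] || a$chrom[i] != b$chrom[j] ||
        a$type[i] != b$type[j]) next
    pa <- seq(a$start[i], a$end[i]); pb <- seq(b$start[j], b$end[j])
    o <- length(intersect(pa, pb))
    if (o > 0 && o / length(pa) >= min_overlap && o / length(pb) >= min_overlap)
      cand <- rbind(cand, data.frame(i = i, j = j, o = o))
  }
  if (is.null(cand)) return(NULL)
  cand <- cand[order(-cand$o, a$start[cand$i], b$start[cand$j]), , drop = FALSE]
  ua <- logical(nrow(a)); ub <- logical(nrow(b)); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!ua[cand$i[k]] && !ub[cand$j[k]]) {
      keep[k] <- TRUE; ua[cand$i[k]] <- TRUE; ub[cand$j[k]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  res <- data.frame(sample_id = a$sample_id[cand$i], chrom = a$chrom[cand$i],
                    start = pmax(a$start[cand$i], b$start[cand$j]),
                    end = pmin(a$end[cand$i], b$end[cand$j]),
                    type = a$type[cand$i], stringsAsFactors = FALSE)
  res <- res[order(res$sample_id, res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-base coverage mask oracle on [1, limit]
oracle_mask <- function(calls, min_support, limit) {
  out <- NULL
  for (ch in unique(calls$chrom)) {
    d <- calls[calls$chrom == ch, , drop = FALSE]
    cov <- integer(limit)
    for (i in seq_len(nrow(d)))
      cov[d$start[i]:d$end[i]] <- cov[d$start[i]:d$end[i]] + 1L
    hit <- cov >= min_support
    if (!any(hit)) next
    r <- rle(hit)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    out <- rbind(out, data.frame(chrom = ch, start = starts[r$values],
                                 end = ends[r$values],
                                 stringsAsFactors = FALSE))
  }
  out
}

random_calls <- function(n, sample_id = "S1", chroms = c("chr1", "chr2"),
                         max_pos = 100000, max_len = 5000, caller = "A") {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(sample_id = sample_id, chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len - 1L,
             type = sample(c("deletion", "duplication"), n, replace = TRUE),
             n_snps = sample(5:50, n, replace = TRUE),
             confidence = round(runif(n, 5, 60), 2),
             caller = caller, stringsAsFactors = FALSE)
}

make_call <- function(chrom = "chr1", start, end, type = "deletion",
                      sample_id = "S1", n_snps = 20L, confidence = 30,
                      caller = "A") {
  data.frame(sample_id = sample_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), type = type, n_snps = n_snps,
             confidence = confidence, caller = caller,
             stringsAsFactors = FALSE)
}
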