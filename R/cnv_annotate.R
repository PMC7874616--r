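#' Percentage of a reference region covered by a CNV
#'
#' `100 * intersection / reference length` with 1-based inclusive lengths,
#' rounded half-up to two decimals — the convention used for the "percent
#' overlap of the reference CNV" column in clinical-report tables. Returns 0
#' for disjoint intervals or different chromosomes; 100 exactly when the
#' reference is contained in the CNV.
#'
#' @param cnv one-row CNV call data.frame (or list) with `chrom`, `start`,
#'   `end`
#' @param region one-row reference data.frame (or list) with `chrom`,
#'   `start`, `end`
#' @return percentage in \[0, 100\]
#' @export
pct_overlap_of_reference <- function(cnv, region) {
  if (cnv$chrom != region$chrom) return(0)
  o <- overlap_len(cnv$start, cnv$end, region$start, region$end)
  round_half_up(100 * o / ivl_len(region$start, region$end), 2)
}

#' Match a CNV against a pathogenic CNV region
#'
#' Pathogenic neurodevelopmental CNV regions come in two kinds. Regions with
#' one or more critical genes are hit by any (>= 1 bp) overlap with a
#' critical-gene exon (falling back, with a warning, to the whole gene
#' interval when exon structure is absent). Regions without a critical gene
#' are hit when the CNV covers at least `threshold` (default 80%) of the
#' reference region. The CNV's type must satisfy the region's dosage
#' constraint (`type_constraint` of `"deletion"`, `"duplication"` or
#' `"either"`); a mismatch is never a hit.
#'
#' @param cnv one-row CNV call (list or data.frame row)
#' @param region a pathogenic-region list with `chrom`, `start`, `end`,
#'   optional `type_constraint` and `critical_genes` (a data.frame with
#'   `chrom`, `start`, `end` per gene, optional `exons` list column of
#'   data.frames with `start`/`end`)
#' @param threshold fraction of the reference required for critical-gene-free
#'   regions (default 0.8)
#' @return list with `hit` (logical), `pct_of_reference`, and `rule_used`
#'   (`"critical_gene"` or `"region_80pct"`; `NA` when no hit)
#' @export
match_pathogenic <- function(cnv, region, threshold = 0.8) {
  pct <- pct_overlap_of_reference(cnv, region)
  constraint <- region$type_constraint %||% "either"
  if (!constraint %in% c("either", cnv$type))
    return(list(hit = FALSE, pct_of_reference = pct, rule_used = NA_character_))

  cg <- region$critical_genes
  if (!is.null(cg) && NROW(cg) > 0L) {
    hit <- FALSE
    for (g in seq_len(nrow(cg))) {
      if (cg$chrom[g] != cnv$chrom) next
      exons <- if ("exons" %in% names(cg)) cg$exons[[g]] else NULL
      if (is.null(exons) || NROW(exons) == 0L) {
        warning("critical gene without exon structure; using the gene interval",
                call. = FALSE)
        exons <- data.frame(start = cg$start[g], end = cg$end[g])
      }
      if (any(overlap_len(cnv$start, cnv$end, exons$start, exons$end) > 0)) {
        hit <- TRUE
        break
      }
    }
    return(list(hit = hit, pct_of_reference = pct,
                rule_used = if (hit) "critical_gene" else NA_character_))
  }
  hit <- pct >= 100 * threshold
  list(hit = hit, pct_of_reference = pct,
       rule_used = if (hit) "region_80pct" else NA_character_)
}

#' Match a CNV against a gene model
#'
#' Deletions hit a gene on any (>= 1 bp) overlap with a coding exon;
#' duplications hit only when the whole gene interval is contained in the
#' CNV (100% overlap required). `pct_of_gene` is the percentage of the gene
#' interval intersected by the CNV, rounded to the nearest integer for
#' reporting.
#'
#' @param cnv one-row CNV call
#' @param gene gene-model list with `chrom`, `gene_start`, `gene_end` and an
#'   `exons` data.frame with `start`/`end`
#' @return list with `hit`, `pct_of_gene`, `rule_used` (`"exon_any"` or
#'   `"full_gene"`; `NA` when no hit)
#' @export
match_gene <- function(cnv, gene) {
  if (cnv$chrom != gene$chrom)
    return(list(hit = FALSE, pct_of_gene = 0, rule_used = NA_character_))
  glen <- ivl_len(gene$gene_start, gene$gene_end)
  pct <- round_half_up(
    100 * overlap_len(cnv$start, cnv$end, gene$gene_start, gene$gene_end) / glen)
  if (cnv$type == "deletion") {
    exons <- gene$exons
    hit <- !is.null(exons) && NROW(exons) > 0L &&
      any(overlap_len(cnv$start, cnv$end, exons$start, exons$end) > 0)
    list(hit = hit, pct_of_gene = pct,
         rule_used = if (hit) "exon_any" else NA_character_)
  } else {
    hit <- cnv$start <= gene$gene_start && cnv$end >= gene$gene_end
    list(hit = hit, pct_of_gene = pct,
         rule_used = if (hit) "full_gene" else NA_character_)
  }
}

#' Assign cytoband labels to a CNV
#'
#' Returns the band(s) covering at least 50% of the CNV's length. A CNV
#' interior to one band yields that band; a CNV straddling a boundary yields
#' the majority band, or both bands (flagged ambiguous via the attribute
#' `ambiguous`) on an exact 50/50 split.
#'
#' @param cnv one-row CNV call
#' @param cytobands data.frame with `chrom`, `start`, `end`, `name` tiling
#'   each chromosome
#' @return character vector of band names, with attribute `ambiguous`
#' @export
annotate_cytoband <- function(cnv, cytobands) {
  b <- cytobands[cytobands$chrom == cnv$chrom, , drop = FALSE]
  assert_that(nrow(b) > 0L, "no cytobands for chromosome ", cnv$chrom)
  frac <- overlap_len(cnv$start, cnv$end, b$start, b$end) /
    ivl_len(cnv$start, cnv$end)
  hits <- b$name[frac >= 0.5]
  structure(hits, ambiguous = length(hits) > 1L)
}

#' Annotate a call table against a pathogenic-region list
#'
#' Vectorized driver over [match_pathogenic()]: one output row per
#' (CNV, region) hit.
#'
#' @param calls CNV call data.frame
#' @param regions list of pathogenic regions (each as for
#'   [match_pathogenic()], with a `name` field)
#' @param threshold passed to [match_pathogenic()]
#' @return data.frame with the call columns plus `region`, `rule_used` and
#'   `pct_of_reference`
#' @export
annotate_pathogenic <- function(calls, regions, threshold = 0.8) {
  validate_calls(calls)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cnv <- calls[i, ]
    for (r in regions) {
      m <- match_pathogenic(cnv, r, threshold)
      if (m$hit)
        rows[[length(rows) + 1L]] <- cbind(
          cnv, data.frame(region = r$name %||% NA_character_,
                          rule_used = m$rule_used,
                          pct_of_reference = m$pct_of_reference,
                          stringsAsFactors = FALSE))
    }
  }
  if (!length(rows))
    return(cbind(calls[0, ], data.frame(region = character(),
                                        rule_used = character(),
                                        pct_of_reference = numeric())))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Report large CNVs without a pathogenic hit, flagging familial sharing
#'
#' Lists retained CNVs longer than `min_length_bp` (strict `>`) in carriers
#' without any pathogenic-region hit, and flags apparent inheritance when
#' first-degree relatives carry same-type CNVs with reciprocal overlap of at
#' least `share_overlap`.
#'
#' @param audits filter-audit data.frame from [filter_cnvs()]
#' @param pathogenic_hits data.frame from [annotate_pathogenic()] (used to
#'   exclude carriers of a pathogenic CNV)
#' @param pedigree data.frame with `sample_id`, `father_id`, `mother_id`
#'   (`NA`/`"0"` for founders); full siblings share both parents
#' @param min_length_bp length cutoff in bp (default 1e6)
#' @param share_overlap reciprocal-overlap fraction for familial sharing
#'   (default 0.5)
#' @return data.frame of large CNVs with `shared_with` (comma-separated
#'   first-degree relatives carrying a matching CNV, `""` if none)
#' @export
report_large_and_familial <- function(audits, pathogenic_hits, pedigree,
                                      min_length_bp = 1000000L,
                                      share_overlap = 0.5) {
  retained <- audits[audits$status == "retained", , drop = FALSE]
  path_carriers <- unique(pathogenic_hits$sample_id)
  big <- retained[ivl_len(retained$start, retained$end) > min_length_bp &
                    !retained$sample_id %in% path_carriers, , drop = FALSE]
  if (nrow(big) == 0L) {
    big$shared_with <- character(0)
    return(big)
  }

  ped <- pedigree
  norm <- function(x) ifelse(is.na(x) | x %in% c("0", ""), NA_character_, x)
  ped$father_id <- norm(ped$father_id); ped$mother_id <- norm(ped$mother_id)
  first_degree <- function(id) {
    row <- ped[ped$sample_id == id, , drop = FALSE]
    rel <- character()
    if (nrow(row)) {
      rel <- c(rel, row$father_id, row$mother_id)
      sibs <- ped$sample_id[!is.na(ped$father_id) & !is.na(ped$mother_id) &
                              ped$father_id %in% row$father_id &
                              ped$mother_id %in% row$mother_id]
      rel <- c(rel, setdiff(sibs, id))
    }
    rel <- c(rel, ped$sample_id[!is.na(ped$father_id) & ped$father_id == id],
             ped$sample_id[!is.na(ped$mother_id) & ped$mother_id == id])
    unique(rel[!is.na(rel)])
  }

  big$shared_with <- vapply(seq_len(nrow(big)), function(i) {
    rel <- first_degree(big$sample_id[i])
    other <- retained[retained$sample_id %in% rel &
                        retained$type == big$type[i] &
                        retained$chrom == big$chrom[i], , drop = FALSE]
    if (nrow(other) == 0L) return("")
    o <- overlap_len(big$start[i], big$end[i], other$start, other$end)
    ok <- o / ivl_len(big$start[i], big$end[i]) >= share_overlap &
      o / ivl_len(other$start, other$end) >= share_overlap
    paste(unique(other$sample_id[ok]), collapse = ",")
  }, character(1))
  rownames(big) <- NULL
  big
}
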