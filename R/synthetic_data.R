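# Synthetic cohort generator: every input the pipeline consumes, with
# planted ground truth, generated in a miniature genome so the full
# pipeline is testable at desk scale without any restricted-access data.

#' Simulation configuration
#'
#' All randomness flows from `seed` through labelled sub-streams (one per
#' generator stage), so each artifact is individually reproducible and a
#' fixed seed gives byte-identical output. Defaults emulate a small
#' family-based SNP-array cohort: trio/quad families with a diagnosed child,
#' a mini-genome of five 50-Mb chromosomes, a dosage panel of common
#' biallelic variants, and caller noise (fragmentation, boundary jitter,
#' one-caller false positives) typical of array CNV callers.
#'
#' @param seed integer master seed
#' @param n_families number of families (trio or quad)
#' @param n_unrelated number of unrelated undiagnosed children
#' @param quad_prob probability a family has a second (undiagnosed) child
#' @param group_pgs_shifts named numeric vector of group mean PGS shifts in
#'   control-SD units; the `ASD` entry is applied at the family level (both
#'   parents' latent mean), the `UNR` entry directly to unrelated children
#' @param ptdt_shift planted over-transmission: added to every child's score
#'   on top of the mid-parental mean, in score-SD units (default 0, null)
#' @param pgs_r2 fraction of phenotype variance attributable to the PGS
#' @param n_variants number of variants in the scoring panel
#' @param cnv_truth optional data.frame of planted CNVs (`carrier`, `chrom`,
#'   `start`, `end`, `type`); `NULL` auto-plants `n_auto_cnvs` CNVs
#' @param n_auto_cnvs number of auto-planted CNVs (default 8)
#' @param fragmentation_rate probability a caller reports a true CNV as >= 2
#'   fragments
#' @param boundary_jitter_bp uniform jitter applied to each reported endpoint
#' @param fp_rate expected spurious calls per sample per caller (Poisson)
#' @param detection_rate probability a true CNV appears in a caller's view
#' @param max_frag_gap_bp maximum gap between fragments of a split CNV
#' @param common_region_specs optional data.frame (`chrom`, `start`, `end`,
#'   `freq`) of polymorphic common-CNV regions carried at population
#'   frequency `freq`
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param pop_probs named probability vector over ancestry populations
#' @param qc_outlier_samples sample ids planted as intensity-QC outliers
#' @param ibd_mode `"auto"` (genotype-based when `n_variants >= 2000`, else
#'   relationship-typical distributions), `"genotype"` or `"distribution"`
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L, n_families = 10L, n_unrelated = 5L,
                       quad_prob = 0.3,
                       group_pgs_shifts = c(ASD = 0.3),
                       ptdt_shift = 0, pgs_r2 = 0.04, n_variants = 1000L,
                       cnv_truth = NULL, n_auto_cnvs = 8L,
                       fragmentation_rate = 0.2, boundary_jitter_bp = 500L,
                       fp_rate = 0.1, detection_rate = 1,
                       max_frag_gap_bp = 50000L,
                       common_region_specs = NULL,
                       chrom_lengths = stats::setNames(rep(50000000L, 5),
                                                       paste0("chr", 1:5)),
                       pop_probs = c(EUR = 0.85, SAS = 0.08, EAS = 0.05,
                                     AFR = 0.02),
                       qc_outlier_samples = character(),
                       ibd_mode = c("auto", "genotype", "distribution")) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              n_unrelated = as.integer(n_unrelated), quad_prob = quad_prob,
              group_pgs_shifts = group_pgs_shifts, ptdt_shift = ptdt_shift,
              pgs_r2 = pgs_r2, n_variants = as.integer(n_variants),
              cnv_truth = cnv_truth, n_auto_cnvs = as.integer(n_auto_cnvs),
              fragmentation_rate = fragmentation_rate,
              boundary_jitter_bp = as.integer(boundary_jitter_bp),
              fp_rate = fp_rate, detection_rate = detection_rate,
              max_frag_gap_bp = as.integer(max_frag_gap_bp),
              common_region_specs = common_region_specs,
              chrom_lengths = chrom_lengths, pop_probs = pop_probs,
              qc_outlier_samples = qc_outlier_samples,
              ibd_mode = match.arg(ibd_mode))
  for (f in c("quad_prob", "pgs_r2", "fragmentation_rate", "detection_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_config("config field '", f, "' must be a fraction in [0,1]")
  }
  # fp_rate is a Poisson intensity (expected count per sample per caller)
  if (!is.numeric(cfg$fp_rate) || cfg$fp_rate < 0)
    stop_config("config field 'fp_rate' must be non-negative")
  for (f in c("n_families", "n_unrelated", "n_variants", "n_auto_cnvs",
              "boundary_jitter_bp", "max_frag_gap_bp")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_config("config field '", f, "' must be a non-negative count")
  }
  if (cfg$n_variants == 0L) stop_config("config field 'n_variants' must be positive")
  if (abs(sum(pop_probs) - 1) > 1e-8)
    stop_config("config field 'pop_probs' must sum to 1")
  if (!is.null(common_region_specs) &&
      (any(common_region_specs$freq < 0) || any(common_region_specs$freq > 1)))
    stop_config("config field 'common_region_specs' frequencies must be in [0,1]")
  class(cfg) <- "sim_config"
  cfg
}

# run code under a deterministic sub-stream of the master seed, restoring
# the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# documented stream-splitting scheme: sub-seed = hash(master seed, label),
# kept below 2^31 so it is a valid R integer seed
sub_seed <- function(seed, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Ancestry reference populations of the mini-genome
#'
#' Centroids and SDs of the four reference populations in the synthetic
#' two-PC coordinate space (arbitrary units; populations are well separated
#' at the default 4-SD assignment radius).
#'
#' @return named list of `list(mean, sd)` per population
#' @export
synthetic_populations <- function() {
  list(EUR = list(mean = c(0, 0), sd = c(1, 1)),
       SAS = list(mean = c(12, 0), sd = c(1, 1)),
       EAS = list(mean = c(0, 12), sd = c(1, 1)),
       AFR = list(mean = c(12, 12), sd = c(1, 1)))
}

#' Generate the cohort bundle with planted ground truth
#'
#' Builds the pedigree (trio/quad families plus unrelated children),
#' Mendelian-consistent genotype panel, latent polygenic scores with the
#' configured group shifts, phenotypes with the configured PGS-attributable
#' R2, PC coordinates around population centroids, sex-check statistics,
#' pairwise IBD table, scoring weights, and the truth set (planted CNVs,
#' true relationships, true group means, true R2).
#'
#' @param config a [sim_config()]
#' @return list with `pedigree`, `dosages`, `freq`, `weights`, `scores`,
#'   `phenotypes`, `pcs`, `populations`, `sexcheck`, `ibd`, `truth`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- with_seed(sub_seed(config$seed, "pedigree"), build_pedigree(config))
  n <- nrow(ped)
  if (n == 0L) {
    return(list(pedigree = ped, dosages = matrix(numeric(), 0, 0),
                freq = numeric(), weights = data.frame(),
                scores = data.frame(), phenotypes = data.frame(),
                pcs = data.frame(), populations = synthetic_populations(),
                sexcheck = data.frame(), ibd = data.frame(),
                truth = list(true_cnvs = empty_truth_cnvs(),
                             true_relationships = data.frame(),
                             true_group_means = config$group_pgs_shifts,
                             true_r2 = config$pgs_r2)))
  }

  geno <- with_seed(sub_seed(config$seed, "genotypes"),
                    build_genotypes(ped, config))
  scores <- with_seed(sub_seed(config$seed, "pgs"),
                      build_latent_scores(ped, config))
  phen <- with_seed(sub_seed(config$seed, "phenotype"),
                    build_phenotypes(ped, scores, config))
  pcs <- with_seed(sub_seed(config$seed, "pcs"), build_pcs(ped))
  sexchk <- with_seed(sub_seed(config$seed, "sexcheck"), build_sexcheck(ped))
  rel <- true_relationships(ped)
  ibd <- with_seed(sub_seed(config$seed, "ibd"),
                   build_ibd(ped, rel, geno, config))
  weights <- with_seed(sub_seed(config$seed, "weights"), data.frame(
    variant = colnames(geno$dosages),
    effect_allele = sample(c("A", "C", "G", "T"), config$n_variants, TRUE),
    effect = snap(stats::rnorm(config$n_variants,
                               sd = 1 / sqrt(config$n_variants))),
    stringsAsFactors = FALSE))
  truth_cnvs <- with_seed(sub_seed(config$seed, "cnv_truth"),
                          build_cnv_truth(ped, config))

  list(pedigree = ped, dosages = geno$dosages, freq = geno$freq,
       weights = weights, scores = scores, phenotypes = phen, pcs = pcs,
       populations = synthetic_populations(), sexcheck = sexchk, ibd = ibd,
       truth = list(true_cnvs = truth_cnvs, true_relationships = rel,
                    true_group_means = config$group_pgs_shifts,
                    true_r2 = config$pgs_r2))
}

empty_truth_cnvs <- function() {
  data.frame(sample_id = character(), chrom = character(), start = integer(),
             end = integer(), type = character(), stringsAsFactors = FALSE)
}

build_pedigree <- function(config) {
  rows <- list()
  pops <- names(config$pop_probs)
  for (f in seq_len(config$n_families)) {
    fid <- sprintf("F%03d", f)
    pop <- sample(pops, 1, prob = config$pop_probs)
    quad <- stats::runif(1) < config$quad_prob
    fa <- sprintf("%s_FA", fid); mo <- sprintf("%s_MO", fid)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = c(fa, mo, sprintf("%s_C1", fid),
                    if (quad) sprintf("%s_C2", fid)),
      family_id = fid,
      father_id = c(NA, NA, fa, if (quad) fa),
      mother_id = c(NA, NA, mo, if (quad) mo),
      sex = c("male", "female",
              sample(c("male", "female"), 1 + quad, TRUE)),
      group = c("FTR", "MTR", "ASD", if (quad) "SIB"),
      population = pop, stringsAsFactors = FALSE)
  }
  for (u in seq_len(config$n_unrelated)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("U%03d", u), family_id = sprintf("UF%03d", u),
      father_id = NA_character_, mother_id = NA_character_,
      sex = sample(c("male", "female"), 1),
      group = "UNR", population = sample(pops, 1, prob = config$pop_probs),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), family_id = character(),
                      father_id = character(), mother_id = character(),
                      sex = character(), group = character(),
                      population = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

build_genotypes <- function(ped, config) {
  nv <- config$n_variants
  freq <- snap(stats::runif(nv, 0.05, 0.95))
  dos <- matrix(NA_real_, nrow(ped), nv,
                dimnames = list(ped$sample_id, sprintf("v%05d", seq_len(nv))))
  founder <- is.na(ped$father_id)
  for (i in which(founder))
    dos[i, ] <- stats::rbinom(nv, 2, freq)
  transmit <- function(g) stats::rbinom(nv, 1, g / 2)
  for (i in which(!founder)) {
    fa <- dos[ped$father_id[i], ]; mo <- dos[ped$mother_id[i], ]
    dos[i, ] <- transmit(fa) + transmit(mo)
  }
  list(dosages = dos, freq = freq)
}

build_latent_scores <- function(ped, config) {
  shifts <- config$group_pgs_shifts
  score <- stats::setNames(numeric(nrow(ped)), ped$sample_id)
  for (fid in unique(ped$family_id[!is.na(ped$father_id)])) {
    fam <- ped[ped$family_id == fid, ]
    fam_shift <- unname(shifts["ASD"] %|na|% 0)
    parents <- fam$sample_id[is.na(fam$father_id)]
    score[parents] <- stats::rnorm(length(parents), fam_shift, 1)
    kids <- fam$sample_id[!is.na(fam$father_id)]
    mid <- mean(score[parents])
    score[kids] <- mid + config$ptdt_shift +
      stats::rnorm(length(kids), 0, sqrt(0.5))
  }
  solo <- ped$sample_id[is.na(ped$father_id) & ped$group == "UNR"]
  score[solo] <- stats::rnorm(length(solo),
                              unname(shifts["UNR"] %|na|% 0), 1)
  data.frame(sample_id = ped$sample_id, trait = "synthetic",
             raw_score = snap(unname(score[ped$sample_id])),
             stringsAsFactors = FALSE)
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

build_phenotypes <- function(ped, scores, config) {
  n <- nrow(ped)
  z <- scale(scores$raw_score)[, 1]
  if (!is.finite(stats::sd(scores$raw_score)) || stats::sd(scores$raw_score) == 0)
    z <- rep(0, n)
  child <- !is.na(ped$father_id) | ped$group == "UNR"
  data.frame(sample_id = ped$sample_id,
             age = snap(ifelse(child, stats::runif(n, 2, 17),
                               stats::runif(n, 25, 60)), 2),
             sex = ped$sex,
             phenotype = snap(sqrt(config$pgs_r2) * z +
                                sqrt(1 - config$pgs_r2) * stats::rnorm(n)),
             stringsAsFactors = FALSE)
}

build_pcs <- function(ped) {
  pops <- synthetic_populations()
  coords <- t(vapply(ped$population, function(p)
    stats::rnorm(2, pops[[p]]$mean, pops[[p]]$sd), numeric(2)))
  data.frame(sample_id = ped$sample_id, PC1 = snap(coords[, 1]),
             PC2 = snap(coords[, 2]), stringsAsFactors = FALSE)
}

build_sexcheck <- function(ped) {
  male <- ped$sex == "male"
  xf <- ifelse(male, stats::rnorm(nrow(ped), 0.99, 0.01),
               stats::rnorm(nrow(ped), 0, 0.02))
  data.frame(sample_id = ped$sample_id, reported_sex = ped$sex,
             x_inbreeding_F = snap(xf),
             genome_F = snap(stats::rnorm(nrow(ped), 0.005, 0.005)),
             stringsAsFactors = FALSE)
}

# planted relationship labels for every within-family pair; cross-family
# pairs are unrelated by construction
true_relationships <- function(ped) {
  rows <- list()
  for (fid in unique(ped$family_id)) {
    fam <- ped[ped$family_id == fid, ]
    ids <- fam$sample_id
    if (length(ids) < 2L) next
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      a <- fam[i, ]; b <- fam[j, ]
      rel <- if ((!is.na(b$father_id) && b$father_id == a$sample_id) ||
                 (!is.na(b$mother_id) && b$mother_id == a$sample_id) ||
                 (!is.na(a$father_id) && a$father_id == b$sample_id) ||
                 (!is.na(a$mother_id) && a$mother_id == b$sample_id))
        "parent_offspring"
      else if (!is.na(a$father_id) && !is.na(b$father_id) &&
               a$father_id == b$father_id && a$mother_id == b$mother_id)
        "full_sibling"
      else "unrelated_or_unclassified"   # spouse pair
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = a$sample_id, id2 = b$sample_id, relationship = rel,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id1 = character(), id2 = character(),
                      relationship = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

build_ibd <- function(ped, rel, geno, config, max_unrelated_pairs = 2000L) {
  use_geno <- config$ibd_mode == "genotype" ||
    (config$ibd_mode == "auto" && config$n_variants >= 2000L)
  ids <- ped$sample_id
  pairs <- utils::combn(ids, 2)
  # all within-family pairs are kept; cross-family (unrelated) pairs are
  # capped so the table stays quadratic-free for large cohorts
  fam <- stats::setNames(ped$family_id, ped$sample_id)
  cross <- which(fam[pairs[1, ]] != fam[pairs[2, ]])
  if (length(cross) > max_unrelated_pairs) {
    drop <- sample(cross, length(cross) - max_unrelated_pairs)
    pairs <- pairs[, -drop, drop = FALSE]
  }
  relmap <- stats::setNames(rel$relationship, paste(rel$id1, rel$id2))
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r <- relmap[paste(a, b)] %|na|% "unrelated_or_unclassified"
    z <- if (use_geno) {
      est <- estimate_ibd(geno$dosages[a, ], geno$dosages[b, ], geno$freq)
      c(est$Z0, est$Z1, est$Z2)
    } else draw_ibd_distribution(r)
    z <- snap(z)
    rows[[k]] <- data.frame(id1 = a, id2 = b,
                            Z0 = z[1], Z1 = z[2], Z2 = z[3],
                            PI_HAT = snap(z[3] + z[2] / 2),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# relationship-typical IBD draws (PLINK --genome style expectations with
# small estimation noise), renormalized to the simplex
draw_ibd_distribution <- function(relationship) {
  centre <- switch(relationship,
                   parent_offspring = c(0.002, 0.99, 0.008),
                   full_sibling = c(0.25, 0.5, 0.25),
                   monozygotic = c(0.002, 0.003, 0.995),
                   half_sibling_or_2nd_degree = c(0.5, 0.495, 0.005),
                   c(0.995, 0.004, 0.001))
  z <- pmax(0, stats::rnorm(3, centre, c(0.01, 0.01, 0.003)))
  z / sum(z)
}

build_cnv_truth <- function(ped, config) {
  if (!is.null(config$cnv_truth)) {
    t <- config$cnv_truth
    if (!"sample_id" %in% names(t) && "carrier" %in% names(t))
      names(t)[names(t) == "carrier"] <- "sample_id"
    bad <- setdiff(t$sample_id, ped$sample_id)
    if (length(bad))
      stop_config("cnv_truth carriers not in cohort: ",
                  paste(bad, collapse = ", "))
    return(t[, c("sample_id", "chrom", "start", "end", "type")])
  }
  if (config$n_auto_cnvs == 0L || nrow(ped) == 0L) return(empty_truth_cnvs())
  chroms <- names(config$chrom_lengths)
  rows <- lapply(seq_len(config$n_auto_cnvs), function(i) {
    chrom <- sample(chroms, 1)
    clen <- config$chrom_lengths[[chrom]]
    len <- round(stats::runif(1, 50000, 2000000))
    # keep away from the centromere band (middle 2% of the chromosome) and,
    # on the first chromosome, the MHC-like complex band (90-93%)
    repeat {
      start <- sample.int(clen - len, 1)
      cen <- c(floor(clen * 0.49), ceiling(clen * 0.51))
      bad <- overlap_len(start, start + len - 1L, cen[1], cen[2]) > 0
      if (chrom == chroms[1]) {
        mhc <- c(floor(clen * 0.9), ceiling(clen * 0.93))
        bad <- bad || overlap_len(start, start + len - 1L, mhc[1], mhc[2]) > 0
      }
      if (!bad) break
    }
    data.frame(sample_id = sample(ped$sample_id, 1), chrom = chrom,
               start = as.integer(start), end = as.integer(start + len - 1L),
               type = sample(c("deletion", "duplication"), 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Generate reference tracks for the mini-genome
#'
#' Centromeres (middle 2% of each chromosome), a cytoband tiling (eight
#' bands per chromosome, p41..p11/q11..q41 style), an MHC-like complex
#' region, gene/exon models (one gene planted inside every true CNV so
#' planted CNVs are exonic, plus random background genes), segmental
#' duplications and a benign-CNV catalog (both placed away from planted
#' CNVs), and pathogenic regions derived from the first planted CNVs (the
#' first with a critical gene, the second without).
#'
#' @param config a [sim_config()]
#' @param truth_cnvs the `true_cnvs` data.frame from [generate_cohort()]
#' @param n_random_genes background gene count (default 30)
#' @return named list of track data.frames (`centromeres`, `cytobands`,
#'   `mhc`, `genes`, `exons`, `segdups`, `benign`, `pathogenic`)
#' @export
generate_reference_tracks <- function(config, truth_cnvs,
                                      n_random_genes = 30L) {
  with_seed(sub_seed(config$seed, "tracks"), {
    chroms <- names(config$chrom_lengths)
    lens <- config$chrom_lengths

    centromeres <- data.frame(chrom = chroms,
                              start = as.integer(floor(lens * 0.49)),
                              end = as.integer(ceiling(lens * 0.51)),
                              stringsAsFactors = FALSE)
    cyto <- do.call(rbind, lapply(chroms, function(ch) {
      cuts <- round(seq(1, lens[[ch]] + 1, length.out = 9))
      data.frame(chrom = ch, start = as.integer(cuts[-9]),
                 end = as.integer(cuts[-1] - 1L),
                 name = c(paste0("p", 4:1, 1), paste0("q", 1:4, 1)),
                 stringsAsFactors = FALSE)
    }))
    mhc <- data.frame(chrom = chroms[1],
                      start = as.integer(floor(lens[[1]] * 0.9)),
                      end = as.integer(floor(lens[[1]] * 0.93)),
                      stringsAsFactors = FALSE)
    avoid <- rbind(truth_cnvs[, c("chrom", "start", "end")],
                   centromeres, mhc,
                   if (!is.null(config$common_region_specs))
                     config$common_region_specs[, c("chrom", "start", "end")])

    # genes: one inside each planted CNV (middle 40% of its span, 3 exons)
    genes <- list(); exons <- list()
    add_gene <- function(symbol, chrom, gs, ge) {
      genes[[length(genes) + 1L]] <<- data.frame(
        symbol = symbol, chrom = chrom, start = gs, end = ge,
        stringsAsFactors = FALSE)
      w <- ge - gs + 1L
      ex_s <- as.integer(gs + round(w * c(0.0, 0.45, 0.9)))
      ex_e <- as.integer(pmin(ge, ex_s + max(50L, round(w * 0.08))))
      exons[[length(exons) + 1L]] <<- data.frame(
        symbol = symbol, chrom = chrom, start = ex_s, end = ex_e,
        stringsAsFactors = FALSE)
    }
    if (nrow(truth_cnvs)) {
      for (i in seq_len(nrow(truth_cnvs))) {
        w <- truth_cnvs$end[i] - truth_cnvs$start[i] + 1L
        gs <- as.integer(truth_cnvs$start[i] + round(w * 0.3))
        ge <- as.integer(truth_cnvs$start[i] + round(w * 0.7))
        add_gene(sprintf("TRUTHG%02d", i), truth_cnvs$chrom[i], gs, ge)
      }
    }
    for (i in seq_len(n_random_genes)) {
      ch <- sample(chroms, 1)
      w <- round(stats::runif(1, 5000, 100000))
      gs <- sample.int(lens[[ch]] - w, 1)
      add_gene(sprintf("BG%03d", i), ch, as.integer(gs), as.integer(gs + w))
    }
    genes <- do.call(rbind, genes); exons <- do.call(rbind, exons)

    place_avoiding <- function(n, min_len, max_len) {
      out <- list()
      tries <- 0L
      while (length(out) < n && tries < 1000L) {
        tries <- tries + 1L
        ch <- sample(chroms, 1)
        w <- round(stats::runif(1, min_len, max_len))
        s <- sample.int(lens[[ch]] - w, 1)
        cand <- data.frame(chrom = ch, start = as.integer(s),
                           end = as.integer(s + w), stringsAsFactors = FALSE)
        hit <- track_overlap_len(cand$chrom, cand$start, cand$end, avoid) > 0
        if (!hit) out[[length(out) + 1L]] <- cand
      }
      do.call(rbind, out)
    }
    segdups <- place_avoiding(6L, 50000, 300000)
    benign <- place_avoiding(5L, 30000, 200000)

    pathogenic <- list()
    if (nrow(truth_cnvs) >= 1L) {
      i <- 1L
      pad <- round((truth_cnvs$end[i] - truth_cnvs$start[i]) * 0.1)
      g <- genes[genes$symbol == "TRUTHG01", ]
      pathogenic[[1]] <- list(
        name = "synthetic_region_critical", chrom = truth_cnvs$chrom[i],
        start = max(1L, truth_cnvs$start[i] - pad),
        end = truth_cnvs$end[i] + pad, type_constraint = "either",
        critical_genes = data.frame(
          symbol = g$symbol, chrom = g$chrom, start = g$start, end = g$end,
          stringsAsFactors = FALSE))
    }
    if (nrow(truth_cnvs) >= 2L) {
      i <- 2L
      pathogenic[[2]] <- list(
        name = "synthetic_region_80pct", chrom = truth_cnvs$chrom[i],
        start = truth_cnvs$start[i], end = truth_cnvs$end[i],
        type_constraint = "either", critical_genes = NULL)
    }

    list(centromeres = centromeres, cytobands = cyto, mhc = mhc,
         genes = genes, exons = exons, segdups = segdups, benign = benign,
         pathogenic = pathogenic)
  })
}

#' Generate the two caller views and the intensity-QC table
#'
#' Each planted CNV appears in each caller's view with probability
#' `detection_rate`, possibly fragmented (with probability
#' `fragmentation_rate`, into 2-3 fragments with gaps at most
#' `max_frag_gap_bp`, whose merged span equals the true span) and with
#' endpoints jittered by up to `boundary_jitter_bp`. False positives are
#' drawn per sample per caller (Poisson `fp_rate`) and land in one caller
#' only, so consensus intersection removes them. Common polymorphic regions
#' produce same-carrier calls in both callers at the configured population
#' frequency. Per-sample intensity statistics (LRRSD/BAFSD/GCWF) are drawn
#' from normal models, with `qc_outlier_samples` planted far outside the
#' batch distribution.
#'
#' @param cohort output of [generate_cohort()]
#' @param config the same [sim_config()]
#' @return list with `calls_a`, `calls_b` (CNV call data.frames) and
#'   `intensity_qc`
#' @export
generate_caller_views <- function(cohort, config) {
  truth <- cohort$truth$true_cnvs
  ped <- cohort$pedigree
  chroms <- names(config$chrom_lengths)

  view_for <- function(caller, stream) with_seed(sub_seed(config$seed, stream), {
    rows <- list()
    emit <- function(sample_id, chrom, start, end, type, conf = NULL) {
      start <- max(1L, as.integer(start))
      end <- min(config$chrom_lengths[[chrom]], as.integer(end))
      if (start > end) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample_id, chrom = chrom, start = start, end = end,
        type = type, n_snps = max(10L, as.integer(round((end - start + 1) / 2500))),
        confidence = snap(conf %||% stats::runif(1, 15, 60), 2),
        caller = caller, stringsAsFactors = FALSE)
    }
    jit <- function(x) {
      if (config$boundary_jitter_bp == 0L) return(x)
      x + sample.int(2L * config$boundary_jitter_bp + 1L, length(x),
                     replace = TRUE) - config$boundary_jitter_bp - 1L
    }
    for (i in seq_len(nrow(truth))) {
      if (stats::runif(1) > config$detection_rate) next
      s <- truth$start[i]; e <- truth$end[i]
      if (stats::runif(1) < config$fragmentation_rate && (e - s) > 3L) {
        k <- sample(2:3, 1)
        gapw <- pmin(config$max_frag_gap_bp,
                     floor((e - s + 1) / (2L * k)))
        gapw <- max(1L, gapw)
        # k fragments separated by k-1 gaps of width <= max_frag_gap_bp,
        # jointly spanning exactly [s, e]
        cuts <- s + sort(sample.int(e - s - 1L, 2L * (k - 1L)))
        frag_s <- c(s, cuts[seq(2, length(cuts), 2)] + 1L)
        frag_e <- c(cuts[seq(1, length(cuts), 2)], e)
        # clamp each gap to the configured maximum
        for (g in seq_len(k - 1L)) {
          gap <- frag_s[g + 1L] - frag_e[g] - 1L
          if (gap > gapw) frag_e[g] <- frag_s[g + 1L] - gapw - 1L
        }
        for (g in seq_len(k))
          emit(truth$sample_id[i], truth$chrom[i], jit(frag_s[g]),
               jit(frag_e[g]), truth$type[i])
      } else {
        emit(truth$sample_id[i], truth$chrom[i], jit(s), jit(e),
             truth$type[i])
      }
    }
    if (!is.null(config$common_region_specs)) {
      crs <- config$common_region_specs
      for (r in seq_len(nrow(crs))) {
        # carrier draws come from a region-specific stream shared by both
        # callers, so a carrier's common call appears in both views
        carriers <- with_seed(sub_seed(config$seed, paste0("common", r)),
                              ped$sample_id[stats::runif(nrow(ped)) < crs$freq[r]])
        for (sid in carriers)
          emit(sid, crs$chrom[r], jit(crs$start[r]), jit(crs$end[r]),
               "deletion")
      }
    }
    if (config$fp_rate > 0) {
      for (sid in ped$sample_id) {
        nfp <- stats::rpois(1, config$fp_rate)
        for (k in seq_len(nfp)) {
          ch <- sample(chroms, 1)
          w <- round(stats::runif(1, 25000, 150000))
          st <- sample.int(config$chrom_lengths[[ch]] - w, 1)
          emit(sid, ch, st, st + w, sample(c("deletion", "duplication"), 1))
        }
      }
    }
    if (!length(rows)) return(empty_calls())
    res <- do.call(rbind, rows)
    res <- res[order(res$sample_id, res$chrom, res$start), , drop = FALSE]
    rownames(res) <- NULL
    res
  })

  calls_a <- view_for("A", "caller_a")
  calls_b <- view_for("B", "caller_b")

  qc <- with_seed(sub_seed(config$seed, "intensity"), {
    n <- nrow(ped)
    d <- data.frame(sample_id = ped$sample_id,
                    LRRSD = snap(stats::rnorm(n, 0.12, 0.02)),
                    BAFSD = snap(stats::rnorm(n, 0.04, 0.008)),
                    GCWF = snap(stats::rnorm(n, 0, 0.01)),
                    stringsAsFactors = FALSE)
    out <- d$sample_id %in% config$qc_outlier_samples
    d$LRRSD[out] <- snap(0.12 + 6 * 0.02)
    d
  })

  list(calls_a = calls_a, calls_b = calls_b, intensity_qc = qc)
}

#' Write / read a cohort bundle on disk
#'
#' Serializes every artifact the pipeline consumes to plain-text files in
#' `dir`: caller-A calls as PennCNV-rawcnv text, caller-B calls and all
#' tables as tab-separated files, reference tracks as BED. `read_cohort_bundle`
#' reproduces the in-memory tables exactly (generated floats are rounded at
#' generation time so the text round-trip is lossless).
#'
#' @param cohort output of [generate_cohort()]
#' @param views output of [generate_caller_views()]
#' @param tracks output of [generate_reference_tracks()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_cohort_bundle <- function(cohort, views, tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv_table(cohort$pedigree, p("pedigree.tsv"))
  write_tsv_table(cohort$scores, p("scores.tsv"))
  write_tsv_table(cohort$phenotypes, p("phenotypes.tsv"))
  write_tsv_table(cohort$pcs, p("pcs.tsv"))
  write_tsv_table(cohort$sexcheck, p("sexcheck.tsv"))
  write_tsv_table(cohort$ibd, p("ibd.tsv"))
  write_tsv_table(cohort$weights, p("weights.tsv"))
  dos <- data.frame(sample_id = rownames(cohort$dosages),
                    cohort$dosages, check.names = FALSE)
  write_tsv_table(dos, p("dosages.tsv"))
  write_tsv_table(data.frame(variant = colnames(cohort$dosages),
                             freq = cohort$freq), p("freq.tsv"))
  write_tsv_table(cohort$truth$true_cnvs, p("truth_cnvs.tsv"))
  write_penncnv_rawcnv(views$calls_a, p("caller_a.rawcnv"))
  write_tsv_table(views$calls_b[, c("sample_id", "chrom", "start", "end",
                                    "type", "n_snps", "confidence")],
                  p("caller_b.tsv"))
  write_tsv_table(views$intensity_qc, p("intensity_qc.tsv"))
  for (tr in c("centromeres", "mhc", "segdups", "benign"))
    write_bed_track(tracks[[tr]], p(paste0(tr, ".bed")))
  write_bed_track(tracks$cytobands, p("cytobands.bed"))
  write_tsv_table(tracks$genes, p("genes.tsv"))
  write_tsv_table(tracks$exons, p("exons.tsv"))
  invisible(dir)
}

#' @rdname write_cohort_bundle
#' @export
read_cohort_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  dos <- read_tsv_table(p("dosages.tsv"))
  m <- as.matrix(dos[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- dos$sample_id
  list(pedigree = read_tsv_table(p("pedigree.tsv")),
       scores = read_tsv_table(p("scores.tsv")),
       phenotypes = read_tsv_table(p("phenotypes.tsv")),
       pcs = read_tsv_table(p("pcs.tsv")),
       sexcheck = read_tsv_table(p("sexcheck.tsv")),
       ibd = read_tsv_table(p("ibd.tsv")),
       weights = read_tsv_table(p("weights.tsv")),
       dosages = m,
       freq = read_tsv_table(p("freq.tsv"))$freq,
       truth_cnvs = read_tsv_table(p("truth_cnvs.tsv")),
       calls_a = read_penncnv_rawcnv(p("caller_a.rawcnv")),
       calls_b = read_caller_table(p("caller_b.tsv")),
       intensity_qc = read_tsv_table(p("intensity_qc.tsv")),
       centromeres = read_bed_track(p("centromeres.bed")),
       mhc = read_bed_track(p("mhc.bed")),
       segdups = read_bed_track(p("segdups.bed")),
       benign = read_bed_track(p("benign.bed")),
       cytobands = read_bed_track(p("cytobands.bed")),
       genes = read_tsv_table(p("genes.tsv")),
       exons = read_tsv_table(p("exons.tsv")))
}
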