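#' Read PennCNV-style rawcnv text
#'
#' One call per line, whitespace-separated fields:
#' `chr1:1000-2000  numsnp=25  length=1,001  state2,cn=1  SAMPLE  startsnp=..
#' endsnp=.. conf=15.5`. Only the region, `numsnp`, copy-number state, sample
#' and `conf` fields are consumed; state/cn encodes deletion (cn < 2) versus
#' duplication (cn > 2). Coordinates are kept 1-based inclusive as printed.
#'
#' @param path path to a rawcnv text file
#' @return a CNV call data.frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `type`, `n_snps`, `confidence`, `caller` (set to `"A"`)
#' @export
read_penncnv_rawcnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_calls())
  parse_one <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    m <- regmatches(f[1], regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", f[1]))[[1]]
    assert_that(length(m) == 4L, "malformed rawcnv region field: ", f[1])
    numsnp <- sub("^numsnp=", "", f[grepl("^numsnp=", f)][1])
    cnf <- f[grepl("^state[0-9]+,cn=[0-9]+$", f)][1]
    cn <- as.integer(sub("^state[0-9]+,cn=", "", cnf))
    conf <- f[grepl("^conf=", f)]
    sample_field <- f[!grepl("=", f) & seq_along(f) > 1][1]
    data.frame(sample_id = sample_field, chrom = m[2],
               start = as.integer(gsub(",", "", m[3])),
               end = as.integer(gsub(",", "", m[4])),
               type = if (cn < 2L) "deletion" else "duplication",
               n_snps = as.integer(gsub(",", "", numsnp)),
               confidence = if (length(conf)) as.numeric(sub("^conf=", "", conf[1])) else NA_real_,
               caller = "A", stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(lines, parse_one))
}

#' Write calls in PennCNV-style rawcnv text
#' @param calls CNV call data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_penncnv_rawcnv <- function(calls, path) {
  validate_calls(calls)
  cn <- ifelse(calls$type == "deletion", 1L, 3L)
  state <- ifelse(calls$type == "deletion", 2L, 5L)
  lines <- sprintf("%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s conf=%s",
                   calls$chrom, calls$start, calls$end,
                   ifelse(is.na(calls$n_snps), 0L, calls$n_snps),
                   calls$end - calls$start + 1L, state, cn, calls$sample_id,
                   ifelse(is.na(calls$confidence), "NA",
                          format(calls$confidence, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a generic tab-separated caller table
#'
#' Expects a header with at least `sample`/`sample_id`, `chrom`, `start`,
#' `end`, `type` columns; `type` accepts `del`/`dup` abbreviations.
#' Coordinates are taken as 1-based inclusive.
#'
#' @param path path to a tab-separated call file
#' @param caller caller label stored in the `caller` column
#' @return a CNV call data.frame
#' @export
read_caller_table <- function(path, caller = "B") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("sample" %in% names(d) && !"sample_id" %in% names(d))
    names(d)[names(d) == "sample"] <- "sample_id"
  d$type <- c(del = "deletion", dup = "duplication",
              deletion = "deletion", duplication = "duplication")[d$type]
  d$caller <- caller
  if (!"n_snps" %in% names(d)) d$n_snps <- NA_integer_
  if (!"confidence" %in% names(d)) d$confidence <- NA_real_
  validate_calls(d)
  d[, c("sample_id", "chrom", "start", "end", "type", "n_snps",
        "confidence", "caller")]
}

#' Read a BED track as 1-based inclusive intervals
#'
#' BED is 0-based half-open; on read `start` becomes `bed_start + 1` and
#' `end` stays `bed_end`. Columns beyond the third are kept (4th = `name`).
#'
#' @param path path to a BED file (plain text, no header)
#' @return data.frame with `chrom`, `start`, `end` and optional `name`
#' @export
read_bed_track <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  out <- data.frame(chrom = d[[1]], start = as.integer(d[[2]]) + 1L,
                    end = as.integer(d[[3]]), stringsAsFactors = FALSE)
  if (ncol(d) >= 4) out$name <- as.character(d[[4]])
  out
}

#' Write 1-based inclusive intervals as BED
#' @param track data.frame with `chrom`, `start`, `end`, optional `name`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_bed_track <- function(track, path) {
  cols <- data.frame(track$chrom, track$start - 1L, track$end)
  if ("name" %in% names(track)) cols$name <- track$name
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_tsv_table
#' @param x data.frame to write
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write plain tab-separated tables with a header
#'
#' Thin wrappers fixing the dialect (tab separator, no quoting, header row)
#' used for every tabular artifact the pipeline emits.
#'
#' @param path file path
#' @return `read_tsv_table`: a data.frame
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
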