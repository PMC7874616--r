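# Internal helpers shared across modules. Coordinates are 1-based inclusive
# throughout the package; BED input/output is converted at the boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed tables in clinical-genetics
#' reports use conventional half-up rounding, so percentage columns are
#' produced with this helper.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# round to `digits` decimals and snap to the decimal-parse fixpoint, so a
# value written as text and read back is bit-identical to the one in memory
snap <- function(x, digits = 6) {
  as.numeric(format(round(x, digits), digits = 15, scientific = FALSE))
}

# inclusive length of the intersection of [s1,e1] and [s2,e2]; 0 when disjoint
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# inclusive interval length
ivl_len <- function(start, end) end - start + 1

stop_config <- function(...) {
  stop(structure(class = c("cnvpgs_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# total length of [start,end] covered by the union of track intervals on the
# same chromosome; track is a data.frame with chrom/start/end (1-based incl.)
track_overlap_len <- function(chrom, start, end, track) {
  if (is.null(track) || nrow(track) == 0L) return(0L)
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(t) == 0L) return(0L)
  red <- IRanges::reduce(IRanges::IRanges(t$start, t$end))
  ints <- IRanges::intersect(red, IRanges::IRanges(start, end))
  sum(IRanges::width(ints))
}

# validate a CNV call table (the package's central container)
validate_calls <- function(calls, require_cols = character()) {
  needed <- c("sample_id", "chrom", "start", "end", "type", require_cols)
  missing <- setdiff(needed, names(calls))
  assert_that(length(missing) == 0L,
              "call table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(calls)) {
    assert_that(all(calls$start <= calls$end), "found call with start > end")
    assert_that(all(calls$type %in% c("deletion", "duplication")),
                "type must be 'deletion' or 'duplication'")
  }
  invisible(calls)
}

# canonical empty call table
empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = integer(), end = integer(), type = character(),
             n_snps = integer(), confidence = numeric(), caller = character(),
             stringsAsFactors = FALSE)
}
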