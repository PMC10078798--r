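#' Construct a genomic interval table
#'
#' Intervals are the atom of every coordinate-based operation in the package.
#' They use the BED convention throughout: 0-based, half-open `[start, end)`.
#' Conversions to and from other conventions (1-based GWAS catalog positions,
#' 1-based closed `GRanges`) happen only at I/O boundaries.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end numeric vectors of 0-based half-open coordinates with
#'   `0 <= start < end`.
#' @param label optional character vector (e.g. a chromatin-state label);
#'   `NA` when absent.
#' @param strand optional character vector in `+`, `-`, `.`; enhancers are
#'   strandless so all overlap operations ignore it.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`,
#'   `strand`, one row per interval, input order preserved.
#' @examples
#' genomic_intervals("chr1", 100, 200, label = "8_EnhA")
#' @export
genomic_intervals <- function(chrom = character(), start = numeric(),
                              end = numeric(), label = NA_character_,
                              strand = ".") {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   label = rep_len(as.character(label), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, where = "intervals") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(where, ": missing column(s) ", paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop(where, ": empty chromosome name")
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad))
    stop(where, ": invalid coordinates (need 0 <= start < end) at row ", bad[1])
  invisible(df)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             label = character(), strand = character(),
             stringsAsFactors = FALSE)
}

# GRanges round-trip helpers: BED half-open <-> 1-based closed. A shared
# seqlevel universe is forced so set operations see both operands' chroms.
as_granges <- function(df, seqlevels = NULL) {
  lv <- unique(c(seqlevels, df$chrom))
  if (length(lv) == 0) lv <- "none"
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = lv),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

from_granges <- function(gr) {
  if (length(gr) == 0) return(empty_intervals())
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = as.numeric(GenomicRanges::start(gr)) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             label = NA_character_,
             strand = ".",
             stringsAsFactors = FALSE)
}

#' Merge intervals into a maximal non-overlapping cover
#'
#' bedtools-merge semantics: per chromosome the output is sorted and covers
#' exactly the union of the input bases; intervals that touch
#' (`end == next start`) are fused. Labels and strand are dropped.
#'
#' @param ivs interval `data.frame` (see [genomic_intervals()]).
#' @return Merged interval `data.frame`, sorted by `(chrom, start)`.
#' @export
merge_intervals <- function(ivs) {
  validate_intervals(ivs)
  if (nrow(ivs) == 0) return(empty_intervals())
  out <- from_granges(GenomicRanges::reduce(as_granges(ivs)))
  sort_intervals(out)
}

sort_intervals <- function(out) {
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract one interval set from another, base by base
#'
#' bedtools-subtract semantics: every base covered by `a` and not by `b`,
#' reported as maximal intervals. An interval of `a` partially covered by `b`
#' is trimmed or split, never dropped whole.
#'
#' @param a,b interval `data.frame`s.
#' @return Merged interval `data.frame` covering `a \ b`.
#' @export
subtract_intervals <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (nrow(a) == 0) return(empty_intervals())
  if (nrow(b) == 0) return(merge_intervals(a))
  lv <- unique(c(a$chrom, b$chrom))
  sort_intervals(from_granges(GenomicRanges::setdiff(as_granges(a, lv), as_granges(b, lv))))
}

#' Intersect two interval sets base by base
#'
#' @param a,b interval `data.frame`s.
#' @return Merged interval `data.frame` covering the bases present in both.
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals())
  lv <- unique(c(a$chrom, b$chrom))
  sort_intervals(from_granges(GenomicRanges::intersect(as_granges(a, lv), as_granges(b, lv))))
}

#' Does a query interval overlap any target by at least `min_bp` bases?
#'
#' Overlap is evaluated against each target individually (half-open
#' coordinates, strand ignored): `TRUE` iff some single target shares at least
#' `min_bp` bases with the query.
#'
#' @param query a single-row interval `data.frame` (or a list/row with
#'   `chrom`, `start`, `end`).
#' @param targets interval `data.frame`.
#' @param min_bp minimum shared bases with one target, `>= 1`.
#' @return logical scalar.
#' @export
overlaps_any <- function(query, targets, min_bp = 1) {
  stopifnot(min_bp >= 1)
  q <- as.data.frame(query)[1, , drop = FALSE]
  validate_intervals(q, "query"); validate_intervals(targets, "targets")
  if (nrow(targets) == 0) return(FALSE)
  same <- targets[targets$chrom == q$chrom, , drop = FALSE]
  if (nrow(same) == 0) return(FALSE)
  ov <- pmin(q$end, same$end) - pmax(q$start, same$start)
  any(ov >= min_bp)
}

#' Per-pair overlap hits between two interval sets
#'
#' Internal workhorse behind enhancer-to-gene assignment: returns the index
#' pairs `(query i, subject j)` whose intervals share at least `min_bp` bases.
#'
#' @noRd
overlap_pairs <- function(query, subject, min_bp = 1) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(q = integer(), s = integer()))
  lv <- unique(c(query$chrom, subject$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges(query, lv),
                                      as_granges(subject, lv),
                                      minoverlap = min_bp)
  data.frame(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
}
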