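# Enhancer extraction from chromatin-state segmentations. In the 18-state
# model used here, states 8-10 mark strong enhancers; the strong-enhancer set
# of a sample is the merged union of those segments. A tissue-specific set is
# what remains of the target tissue's strong enhancers after comparison
# against the strong enhancers of background (non-craniofacial) tissues.

#' Construct an enhancer set
#'
#' @param sample_id originating tissue/sample.
#' @param kind `"strong"` or `"tissue_specific"`.
#' @param intervals interval `data.frame`; merged (sorted, non-overlapping)
#'   or an error.
#' @param provenance character vector of contributing state labels.
#' @return An `EnhancerSet` (list with the four fields above).
#' @export
enhancer_set <- function(sample_id, kind, intervals, provenance = character()) {
  kind <- match.arg(kind, c("strong", "tissue_specific"))
  validate_intervals(intervals)
  if (nrow(intervals) > 1) {
    o <- order(intervals$chrom, intervals$start)
    intervals <- intervals[o, , drop = FALSE]
    same <- intervals$chrom[-1] == intervals$chrom[-nrow(intervals)]
    if (any(same & intervals$start[-1] < intervals$end[-nrow(intervals)]))
      stop("enhancer set '", sample_id, "': intervals must be non-overlapping")
  }
  rownames(intervals) <- NULL
  structure(list(sample_id = sample_id, kind = kind, intervals = intervals,
                 provenance = provenance),
            class = "EnhancerSet")
}

#' @export
print.EnhancerSet <- function(x, ...) {
  cat(sprintf("EnhancerSet '%s' (%s): %d intervals, %s bp\n",
              x$sample_id, x$kind, nrow(x$intervals),
              format(sum(x$intervals$end - x$intervals$start), big.mark = ",")))
  invisible(x)
}

#' Extract strong enhancers from a segmentation
#'
#' Selects all segments whose state is in `strong_states` (defaults 8, 9, 10,
#' the strong-enhancer states of the 18-state model) and merges them; adjacent
#' strong segments fuse into one enhancer.
#'
#' @param track `SegmentationTrack` from [read_segmentation()].
#' @param strong_states integer set of enhancer states; must lie within the
#'   track's state model.
#' @return `EnhancerSet` of kind `"strong"`. An empty segmentation yields an
#'   empty set, not an error.
#' @export
extract_strong_enhancers <- function(track, strong_states = c(8, 9, 10)) {
  stopifnot(inherits(track, "SegmentationTrack"))
  strong_states <- as.integer(strong_states)
  if (any(strong_states < 1 | strong_states > track$state_model))
    stop("strong_states must lie in [1, ", track$state_model, "]")
  segs <- track$segments
  hit <- segs[segs$state %in% strong_states, , drop = FALSE]
  enhancer_set(track$sample_id, "strong", merge_intervals(hit),
               provenance = unique(hit$label))
}

#' Derive tissue-specific enhancers by multi-tissue subtraction
#'
#' An enhancer of the target tissue is tissue-specific when no background
#' tissue has a strong enhancer in the same place. Two notions of "same
#' place" are supported: `remove_whole` (default) drops a target enhancer
#' entirely as soon as it shares `min_bp` bases with any background enhancer
#' -- an element either is or is not unique; `trim` performs base-wise
#' subtraction, keeping the uncovered pieces.
#'
#' @param target `EnhancerSet` of kind `"strong"`.
#' @param backgrounds list of `EnhancerSet`s of kind `"strong"`.
#' @param mode `"remove_whole"` or `"trim"`.
#' @param min_bp minimum shared bases that disqualify an enhancer
#'   (`remove_whole` mode only).
#' @return `EnhancerSet` of kind `"tissue_specific"`; every base of the result
#'   is also in `target`. Empty `backgrounds` returns the target re-tagged,
#'   with a warning.
#' @export
tissue_specific_enhancers <- function(target, backgrounds,
                                      mode = c("remove_whole", "trim"),
                                      min_bp = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "EnhancerSet"), target$kind == "strong")
  if (inherits(backgrounds, "EnhancerSet")) backgrounds <- list(backgrounds)
  ok <- vapply(backgrounds, function(b)
    inherits(b, "EnhancerSet") && b$kind == "strong", logical(1))
  if (!all(ok)) stop("backgrounds must be strong EnhancerSets")
  if (length(backgrounds) == 0) {
    warning("no background tissues: tissue-specific set equals the strong set")
    return(enhancer_set(target$sample_id, "tissue_specific", target$intervals,
                        target$provenance))
  }
  bg <- do.call(rbind, lapply(backgrounds, function(b) b$intervals[c("chrom", "start", "end")]))
  tg <- target$intervals
  if (mode == "remove_whole") {
    hits <- overlap_pairs(tg, bg, min_bp = min_bp)
    keep <- if (nrow(tg)) tg[setdiff(seq_len(nrow(tg)), unique(hits$q)), , drop = FALSE]
            else tg
  } else {
    keep <- subtract_intervals(tg, bg)
  }
  enhancer_set(target$sample_id, "tissue_specific", keep, target$provenance)
}

#' Project an enhancer set through a precomputed coordinate map
#'
#' Applies an externally produced cross-assembly map (e.g. from a liftover
#' with a sequence-conservation cutoff) given as blocks
#' `(src_chrom, src_start, src_end) -> (dst_chrom, dst_start, dst_end)`.
#' An enhancer overlapping a source block by at least 1 bp has its overlapping
#' portion projected by block offset; enhancers touching no block are dropped
#' and counted. Source blocks must not overlap one another.
#'
#' @param es `EnhancerSet`.
#' @param cmap `data.frame` with columns `src_chrom`, `src_start`, `src_end`,
#'   `dst_chrom`, `dst_start`, `dst_end` (0-based half-open both sides).
#' @return `EnhancerSet` in destination coordinates, with a `mapping_report`
#'   attribute: `n_input`, `n_mapped`, `n_dropped`.
#' @export
apply_coordinate_map <- function(es, cmap) {
  stopifnot(inherits(es, "EnhancerSet"))
  need <- c("src_chrom", "src_start", "src_end", "dst_chrom", "dst_start", "dst_end")
  miss <- setdiff(need, names(cmap))
  if (length(miss)) stop("coordinate map: missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(cmap) > 0) {
    if (any(cmap$src_start >= cmap$src_end) || any(cmap$dst_start >= cmap$dst_end))
      stop("coordinate map: inverted coordinates")
    src <- data.frame(chrom = cmap$src_chrom, start = cmap$src_start,
                      end = cmap$src_end, stringsAsFactors = FALSE)
    self <- overlap_pairs(src, src)
    if (any(self$q != self$s))
      stop("coordinate map: source blocks overlap")
  } else {
    src <- empty_intervals()
  }
  ivs <- es$intervals
  n_in <- nrow(ivs)
  hits <- overlap_pairs(ivs, src)
  # one destination interval per (enhancer, block) overlap; typical maps give
  # at most one block per enhancer
  out <- if (nrow(hits)) {
    i <- hits$q; j <- hits$s
    lo <- pmax(ivs$start[i], cmap$src_start[j])
    hi <- pmin(ivs$end[i], cmap$src_end[j])
    data.frame(chrom = cmap$dst_chrom[j],
               start = cmap$dst_start[j] + (lo - cmap$src_start[j]),
               end = pmin(cmap$dst_start[j] + (hi - cmap$src_start[j]),
                          cmap$dst_end[j]),
               label = ivs$label[i], strand = ".", stringsAsFactors = FALSE)
  } else empty_intervals()
  res <- enhancer_set(es$sample_id, es$kind, merge_intervals(out), es$provenance)
  attr(res, "mapping_report") <- list(n_input = n_in,
                                      n_mapped = length(unique(hits$q)),
                                      n_dropped = n_in - length(unique(hits$q)))
  res
}
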