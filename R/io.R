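# Readers and writers for the plain-text formats the pipeline consumes:
# BED3/BED4 (enhancers, VISTA elements), ChromHMM dense segmentation BED,
# GWAS-catalog style association TSV, gene table TSV, chrom sizes, and the
# headered marker/DE/module tables. One convention inside the package:
# 0-based half-open; 1-based external positions are converted here and only
# here. Chromosome names are matched exactly -- no "chr" prefix normalization,
# a mismatch should fail loudly rather than be papered over.

#' Read a BED3/BED4 file
#'
#' @param path path to a tab-separated BED file; at least three columns
#'   (`chrom`, `start`, `end`), a fourth column is stored as `label`.
#' @return Interval `data.frame` in file order (see [genomic_intervals()]).
#'   Malformed lines (fewer than 3 fields, non-integer coordinates,
#'   `start >= end`) raise an error naming the line number.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_intervals())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(path, ": line ", which(nf < 3)[1], ": expected >= 3 tab-separated fields")
  chrom <- vapply(parts, `[[`, "", 1)
  s_raw <- vapply(parts, `[[`, "", 2)
  e_raw <- vapply(parts, `[[`, "", 3)
  start <- suppressWarnings(as.numeric(s_raw))
  end <- suppressWarnings(as.numeric(e_raw))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end) | start >= end | start < 0)
  if (length(bad))
    stop(path, ": line ", bad[1], ": malformed coordinates '",
         s_raw[bad[1]], "\t", e_raw[bad[1]], "'")
  label <- ifelse(nf >= 4, vapply(parts, function(p) p[min(4, length(p))], ""), NA_character_)
  data.frame(chrom = chrom, start = start, end = end, label = label,
             strand = ".", stringsAsFactors = FALSE)
}

#' Write intervals as BED3/BED4
#'
#' Writes BED4 when any label is present, else BED3. Round-trips byte-for-byte
#' with [read_bed()] on canonical input.
#'
#' @param ivs interval `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ivs, path) {
  validate_intervals(ivs)
  has_label <- nrow(ivs) > 0 && any(!is.na(ivs$label))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (nrow(ivs) == 0) {
    writeLines(character(), path)
  } else if (has_label) {
    writeLines(paste(ivs$chrom, fmt(ivs$start), fmt(ivs$end),
                     ifelse(is.na(ivs$label), ".", ivs$label), sep = "\t"), path)
  } else {
    writeLines(paste(ivs$chrom, fmt(ivs$start), fmt(ivs$end), sep = "\t"), path)
  }
  invisible(path)
}

#' Parse a chromatin-state label to its state number
#'
#' Accepts bare integers (`"8"`) or ChromHMM dense-BED prefixed labels
#' (`"8_EnhA1"`); the leading integer is authoritative.
#'
#' @param label character vector of state labels.
#' @return integer vector of state numbers; unparseable labels raise an error.
#' @export
parse_state_label <- function(label) {
  m <- regmatches(label, regexpr("^[0-9]+", label))
  bad <- which(!grepl("^[0-9]+", label))
  if (length(bad))
    stop("state label does not start with an integer: '", label[bad[1]], "'")
  as.integer(m)
}

#' Read a ChromHMM-style dense segmentation BED
#'
#' @param path dense segmentation BED (label column = state).
#' @param sample_id identifier for the tissue/sample.
#' @param state_model number of states in the model (15 or 18).
#' @return A `SegmentationTrack`: list with `sample_id`, `segments` (interval
#'   `data.frame` with `state` column, sorted, validated non-overlapping per
#'   chromosome) and `state_model`.
#' @export
read_segmentation <- function(path, sample_id = basename(path), state_model = 18) {
  stopifnot(state_model %in% c(15L, 18L))
  segs <- read_bed(path)
  segmentation_track(sample_id, segs, state_model)
}

#' Assemble and validate a segmentation track
#'
#' @param sample_id sample identifier.
#' @param segments interval `data.frame` whose `label` column carries the
#'   state of each segment.
#' @param state_model 15 or 18.
#' @return `SegmentationTrack` list; segments sorted by `(chrom, start)`.
#'   Overlapping segments on one chromosome, or a state outside
#'   `[1, state_model]`, are load-time errors.
#' @export
segmentation_track <- function(sample_id, segments, state_model = 18) {
  validate_intervals(segments, "segments")
  if (nrow(segments) > 0) {
    if (any(is.na(segments$label)))
      stop("segmentation '", sample_id, "': segment without a state label")
    state <- parse_state_label(segments$label)
    if (any(state < 1 | state > state_model))
      stop("segmentation '", sample_id, "': state ",
           state[which(state < 1 | state > state_model)[1]],
           " outside [1, ", state_model, "]")
    segments$state <- state
    o <- order(segments$chrom, segments$start)
    segments <- segments[o, , drop = FALSE]
    rownames(segments) <- NULL
    same <- segments$chrom[-1] == segments$chrom[-nrow(segments)]
    if (nrow(segments) > 1 &&
        any(same & segments$start[-1] < segments$end[-nrow(segments)]))
      stop("segmentation '", sample_id, "': overlapping segments on one chromosome")
  } else {
    segments$state <- integer()
  }
  structure(list(sample_id = sample_id, segments = segments,
                 state_model = as.integer(state_model)),
            class = "SegmentationTrack")
}

#' Read a GWAS-catalog style association table
#'
#' Positions in the file are 1-based (catalog convention) and converted to the
#' package's 0-based convention at load. Column names are configurable;
#' defaults follow the GWAS Catalog export.
#'
#' @param path tab-separated file with a header row.
#' @param columns named character vector mapping internal fields
#'   (`variant_id`, `chrom`, `pos`, `pvalue`, `trait`) to file column names.
#' @return `data.frame` with columns `variant_id`, `chrom`, `pos` (0-based),
#'   `pvalue`, `trait`.
#' @export
read_gwas_table <- function(path,
                            columns = c(variant_id = "SNPS", chrom = "CHR_ID",
                                        pos = "CHR_POS", pvalue = "P-VALUE",
                                        trait = "MAPPED_TRAIT")) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(unname(columns), names(tab))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  out <- data.frame(variant_id = as.character(tab[[columns[["variant_id"]]]]),
                    chrom = as.character(tab[[columns[["chrom"]]]]),
                    pos = as.numeric(tab[[columns[["pos"]]]]) - 1,
                    pvalue = as.numeric(tab[[columns[["pvalue"]]]]),
                    trait = as.character(tab[[columns[["trait"]]]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$pvalue) | out$pvalue <= 0 | out$pvalue > 1))
    stop(path, ": p-values must lie in (0, 1]")
  if (any(is.na(out$pos) | out$pos < 0))
    stop(path, ": positions must be positive 1-based integers")
  out
}

#' Read a gene annotation table
#'
#' Expects tab-separated columns `gene_id`, `symbol`, `chrom`, `start`, `end`,
#' `strand` and optionally `ortholog_id`. The TSS is derived from the strand
#' (`start` on `+`, `end - 1` on `-`) and checked to lie inside the span.
#'
#' @param path gene table TSV with header.
#' @return `data.frame` of gene records with a derived `tss` column.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!"ortholog_id" %in% names(tab)) tab$ortholog_id <- NA_character_
  gene_records(tab)
}

#' Validate a gene table and derive TSS positions
#'
#' @param tab `data.frame` with `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand` (and optional `ortholog_id`).
#' @return The validated table with `tss` added.
#' @export
gene_records <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id: ", tab$gene_id[duplicated(tab$gene_id)][1])
  if (!all(tab$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(tab$start < 0 | tab$start >= tab$end))
    stop("gene spans must satisfy 0 <= start < end")
  tab$tss <- ifelse(tab$strand == "+", tab$start, tab$end - 1)
  rownames(tab) <- NULL
  tab
}

#' Read a two-column chromosome sizes table
#'
#' @param path TSV with columns chromosome name, length in bp (no header).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop(path, ": expected two columns (chrom, size)")
  sizes <- as.numeric(tab[[2]])
  if (any(is.na(sizes) | sizes <= 0)) stop(path, ": sizes must be positive")
  stats::setNames(sizes, as.character(tab[[1]]))
}

# Generic headered TSV with required columns; shared by the marker/DE/module
# table readers.
read_checked_tsv <- function(path, need) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  tab
}

#' @rdname read_gene_table
#' @details `read_de_table()` expects columns `gene_id`, `log2fc`, `padj`;
#'   `read_marker_table()` expects `gene_id`, `cell_type`, `log2fc`, `padj`;
#'   `read_module_table()` expects `gene_id`, `module`.
#' @export
read_de_table <- function(path) read_checked_tsv(path, c("gene_id", "log2fc", "padj"))

#' @rdname read_gene_table
#' @export
read_marker_table <- function(path)
  read_checked_tsv(path, c("gene_id", "cell_type", "log2fc", "padj"))

#' @rdname read_gene_table
#' @export
read_module_table <- function(path) read_checked_tsv(path, c("gene_id", "module"))
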