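# Linking regulatory elements and variants to genes. Enhancer-to-gene
# assignment follows the basal-plus-extension rule: each gene owns a basal
# domain around its TSS (5 kb upstream / 1 kb downstream by default) extended
# in both directions up to 1 Mb or until it meets a neighbouring gene's basal
# domain; an enhancer is assigned to every gene whose extended domain it
# overlaps. Variant and validated-element proximity use fixed windows
# (500 kbp and 1 Mb by default) measured to the gene span.

#' Build basal-plus-extension regulatory domains
#'
#' The basal domain is a strand-oriented window around the TSS
#' (`basal_up` upstream, `basal_down` downstream). Each side is then extended
#' away from the TSS until the nearest other gene's basal domain edge or
#' `max_extension` from the basal edge, whichever comes first, and clipped to
#' the chromosome. A neighbouring basal domain already overlapping the gene's
#' basal domain blocks extension on that side entirely (the basal domain
#' itself is never shrunk). Genes with identical TSS positions do not truncate
#' each other. Domains may overlap; every gene receives a domain.
#'
#' @param genes gene table from [read_gene_table()] / [gene_records()].
#' @param basal_up,basal_down basal window, bp upstream/downstream of the TSS.
#' @param max_extension maximum extension beyond each basal edge, bp.
#' @param chrom_sizes named vector of chromosome lengths; must cover every
#'   gene's chromosome.
#' @return `data.frame` with `gene_id`, `chrom`, `basal_start`, `basal_end`,
#'   `ext_start`, `ext_end`, `tss`, `strand` (0-based half-open).
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                                     max_extension = 1000000, chrom_sizes) {
  stopifnot(basal_up >= 0, basal_down >= 0, max_extension >= 0)
  miss <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(miss))
    stop("chromosome(s) missing from chrom_sizes: ", paste(miss, collapse = ", "))
  n <- nrow(genes)
  plus <- genes$strand == "+"
  # basal window contains the TSS base on both strands
  b_start <- ifelse(plus, genes$tss - basal_up, genes$tss + 1 - basal_down)
  b_end <- ifelse(plus, genes$tss + basal_down, genes$tss + 1 + basal_up)
  size <- unname(chrom_sizes[genes$chrom])
  b_start <- pmax(0, b_start)
  b_end <- pmin(size, b_end)
  ext_start <- pmax(0, b_start - max_extension)
  ext_end <- pmin(size, b_end + max_extension)
  for (i in seq_len(n)) {
    others <- which(genes$chrom == genes$chrom[i] & genes$tss != genes$tss[i])
    if (!length(others)) next
    os <- b_start[others]; oe <- b_end[others]
    # left: nearest other basal edge at or left of our basal start;
    # an overlapping basal blocks extension at our own edge
    left_edges <- oe[oe <= b_start[i]]
    if (any(os < b_start[i] & oe > b_start[i])) left_edges <- c(left_edges, b_start[i])
    if (length(left_edges)) ext_start[i] <- max(ext_start[i], max(left_edges))
    right_edges <- os[os >= b_end[i]]
    if (any(os < b_end[i] & oe > b_end[i])) right_edges <- c(right_edges, b_end[i])
    if (length(right_edges)) ext_end[i] <- min(ext_end[i], min(right_edges))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             basal_start = b_start, basal_end = b_end,
             ext_start = ext_start, ext_end = ext_end,
             tss = genes$tss, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Assign enhancers to genes via regulatory domains
#'
#' An enhancer is assigned to every gene whose extended regulatory domain it
#' overlaps by at least 1 bp; multi-assignment is allowed.
#'
#' @param enhancers `EnhancerSet` or interval `data.frame`.
#' @param domains regulatory domains from [build_regulatory_domains()].
#' @return list with `counts` (`gene_id`, `n` assigned enhancers, zero rows
#'   included) and `links` (`gene_id`, `enhancer_id`, `distance` = signed
#'   genomic offset of the enhancer midpoint from the TSS).
#' @export
assign_enhancers_to_genes <- function(enhancers, domains) {
  ivs <- if (inherits(enhancers, "EnhancerSet")) enhancers$intervals else enhancers
  validate_intervals(ivs, "enhancers")
  dom_iv <- data.frame(chrom = domains$chrom, start = domains$ext_start,
                       end = domains$ext_end, stringsAsFactors = FALSE)
  hits <- overlap_pairs(ivs, dom_iv)
  eid <- if (nrow(ivs)) ifelse(is.na(ivs$label) | !nzchar(ivs$label),
                               sprintf("%s:%d-%d", ivs$chrom,
                                       as.integer(ivs$start), as.integer(ivs$end)),
                               ivs$label) else character()
  links <- data.frame(
    gene_id = domains$gene_id[hits$s],
    enhancer_id = eid[hits$q],
    distance = floor((ivs$start[hits$q] + ivs$end[hits$q]) / 2) - domains$tss[hits$s],
    stringsAsFactors = FALSE)
  counts <- data.frame(gene_id = domains$gene_id,
                       n = as.integer(tabulate(hits$s, nbins = nrow(domains))),
                       stringsAsFactors = FALSE)
  list(counts = counts, links = links)
}

#' Per-gene strong and tissue-specific enhancer target counts
#'
#' Convenience wrapper running [assign_enhancers_to_genes()] for the strong
#' and the tissue-specific set of one sample.
#'
#' @param strong,specific `EnhancerSet`s (kind `"strong"` /
#'   `"tissue_specific"`).
#' @param domains regulatory domains.
#' @return `data.frame` with `gene_id`, `n_ste`, `n_tse`.
#' @export
gene_enhancer_links <- function(strong, specific, domains) {
  a <- assign_enhancers_to_genes(strong, domains)$counts
  b <- assign_enhancers_to_genes(specific, domains)$counts
  data.frame(gene_id = a$gene_id, n_ste = a$n, n_tse = b$n,
             stringsAsFactors = FALSE)
}

# Distance in bases between a position/span and a gene span, half-open
# coordinates: 0 inside/overlapping, otherwise the coordinate difference
# between the two closest bases (adjacent bases are 1 apart).
span_point_distance <- function(g_start, g_end, pos) {
  ifelse(pos < g_start, g_start - pos,
         ifelse(pos >= g_end, pos - (g_end - 1), 0))
}

span_span_distance <- function(g_start, g_end, e_start, e_end) {
  ifelse(e_end <= g_start, g_start - (e_end - 1),
         ifelse(e_start >= g_end, e_start - (g_end - 1), 0))
}

#' Genes within a window of at least one variant
#'
#' A gene qualifies when the distance between some variant position and the
#' gene (span by default, or TSS) is at most `window` bases, boundary
#' inclusive; same chromosome only. Distance is 0 for a variant inside the
#' gene, otherwise the base-coordinate gap to the nearest gene base.
#'
#' @param genes gene table.
#' @param variants variant table (see [read_gwas_table()]).
#' @param window distance cutoff in bp (default 500 kbp).
#' @param measure `"span"` (default) or `"tss"`.
#' @return character set of qualifying `gene_id`s.
#' @export
genes_near_variants <- function(genes, variants, window = 500000,
                                measure = c("span", "tss")) {
  measure <- match.arg(measure)
  stopifnot(window >= 0)
  if (nrow(genes) == 0 || nrow(variants) == 0) return(character())
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    v <- variants[variants$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(v) == 0) return(FALSE)
    d <- if (measure == "span")
      span_point_distance(genes$start[i], genes$end[i], v$pos)
    else abs(v$pos - genes$tss[i])
    any(d <= window)
  }, logical(1))
  genes$gene_id[hit]
}

#' Genes within a window of at least one interval element
#'
#' As [genes_near_variants()] with span-to-span distance; used for
#' validated-enhancer (VISTA) proximity with the default 1 Mb window.
#'
#' @param genes gene table.
#' @param elements interval `data.frame`.
#' @param window distance cutoff in bp (default 1 Mb).
#' @return character set of qualifying `gene_id`s.
#' @export
genes_near_intervals <- function(genes, elements, window = 1000000) {
  stopifnot(window >= 0)
  validate_intervals(elements, "elements")
  if (nrow(genes) == 0 || nrow(elements) == 0) return(character())
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    e <- elements[elements$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(e) == 0) return(FALSE)
    d <- span_span_distance(genes$start[i], genes$end[i], e$start, e$end)
    any(d <= window)
  }, logical(1))
  genes$gene_id[hit]
}

#' Retain genome-wide significant variants for selected traits
#'
#' Keeps variants with `pvalue <= alpha` (boundary inclusive) whose trait is
#' in `traits` (all traits when empty), then drops exact duplicates of
#' `(variant_id, chrom, pos)`. Multi-position rsIDs are deliberately kept as
#' separate records.
#'
#' @param variants variant table.
#' @param alpha significance threshold (default genome-wide, 5e-8).
#' @param traits character vector of trait tags to keep; empty = all.
#' @return filtered variant table.
#' @export
filter_gwas_variants <- function(variants, alpha = 5e-8, traits = character()) {
  keep <- variants$pvalue <= alpha
  if (length(traits)) keep <- keep & variants$trait %in% traits
  out <- variants[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("variant_id", "chrom", "pos")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain differentially expressed genes
#'
#' Keeps genes with `log2fc` strictly greater than `lfc_min` and adjusted p
#' at most `padj_max` (the thresholds are read literally: strict `>` for fold
#' change, inclusive `<=` for adjusted p).
#'
#' @param de_table `data.frame` with `gene_id`, `log2fc`, `padj`.
#' @param lfc_min fold-change threshold (default 2, strict).
#' @param padj_max adjusted-p threshold (default 0.05, inclusive).
#' @return character set of retained `gene_id`s.
#' @export
filter_de_genes <- function(de_table, lfc_min = 2, padj_max = 0.05) {
  need <- c("gene_id", "log2fc", "padj")
  miss <- setdiff(need, names(de_table))
  if (length(miss)) stop("DE table: missing column(s) ", paste(miss, collapse = ", "))
  if (any(de_table$padj < 0 | de_table$padj > 1, na.rm = TRUE))
    stop("DE table: padj outside [0, 1]")
  keep <- !is.na(de_table$log2fc) & !is.na(de_table$padj) &
    de_table$log2fc > lfc_min & de_table$padj <= padj_max
  unique(de_table$gene_id[keep])
}
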