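# Composite prioritization score for candidate odontogenic loci. Each gene
# accumulates points from eight evidence components:
#   marker gene (0/1), dental-cell-type marker (0/1), GWAS-variant proximity
#   (0/1), targeting-TSE count bucket (0-4), module enrichment flags (0-3),
#   VISTA-element proximity (0/1), tooth-enhancer target (0/1), DEG (0/1);
# maximum total 13. Genes in the grey (unassigned, low-expression) module are
# excluded before scoring; ties are broken by the number of targeting TSEs,
# then lexicographic gene id for full determinism.

#' Points for the targeting-TSE count bucket
#'
#' Piecewise-constant: 0 TSEs = 0, 1-2 = 1, 3-4 = 2, 5-6 = 3, 7 or more = 4.
#'
#' @param n_tse non-negative count(s) of predicted targeting tissue-specific
#'   enhancers.
#' @return integer points in 0..4, vectorized.
#' @export
tse_bucket_points <- function(n_tse) {
  if (any(is.na(n_tse) | n_tse < 0)) stop("n_tse must be non-negative")
  as.integer(ifelse(n_tse >= 7, 4,
              ifelse(n_tse >= 5, 3,
               ifelse(n_tse >= 3, 2,
                ifelse(n_tse >= 1, 1, 0)))))
}

#' The dental-specific cell types of the developing tooth
#'
#' @return character vector: Enamel Knot, Epithelium, Mesenchyme,
#'   Perivascular Cells.
#' @export
dental_cell_types <- function() {
  c("Enamel Knot", "Epithelium", "Mesenchyme", "Perivascular Cells")
}

#' Point for being a marker of a dental-specific cell type
#'
#' @param cell_types character vector of cell types the gene marks.
#' @param dental_types the dental-specific list (default
#'   [dental_cell_types()]).
#' @return 1 if any cell type is dental-specific, else 0.
#' @export
dental_marker_points <- function(cell_types, dental_types = dental_cell_types()) {
  as.integer(length(intersect(cell_types, dental_types)) > 0)
}

#' Points from module enrichment flags
#'
#' One point per enrichment category the gene's module carries
#' (tooth-enhancer targets, dental-phenotype ontology, DEGs), or a single
#' lump point when any flag is set (`scoring = "lump"`).
#'
#' @param flags logical vector/list with elements `enr_te_targets`,
#'   `enr_dental_ontology`, `enr_degs`.
#' @param scoring `"per_category"` (default, 0-3) or `"lump"` (0/1).
#' @return integer points.
#' @export
module_points <- function(flags, scoring = c("per_category", "lump")) {
  scoring <- match.arg(scoring)
  f <- as.logical(unlist(flags[c("enr_te_targets", "enr_dental_ontology", "enr_degs")]))
  f[is.na(f)] <- FALSE
  if (scoring == "per_category") sum(f) else as.integer(any(f))
}

# Column schema of an evidence table; marker_cell_types is a comma-separated
# string so evidence round-trips through TSV.
evidence_columns <- function() {
  c("gene_id", "module", "is_marker", "marker_cell_types", "near_gwas_variant",
    "n_tse", "n_ste", "enr_te_targets", "enr_dental_ontology", "enr_degs",
    "near_vista", "is_te_target", "is_deg")
}

validate_evidence <- function(ev) {
  miss <- setdiff(evidence_columns(), names(ev))
  if (length(miss))
    stop("evidence table: missing column(s) ", paste(miss, collapse = ", "))
  if (any(ev$n_tse < 0 | ev$n_ste < 0)) stop("enhancer counts must be >= 0")
  has_types <- !is.na(ev$marker_cell_types) & nzchar(ev$marker_cell_types)
  if (any(has_types & !ev$is_marker))
    stop("marker_cell_types present for a gene not flagged as marker")
  invisible(ev)
}

#' Score genes from assembled evidence
#'
#' Computes the per-gene score decomposition: one point each for marker gene,
#' dental-cell-type marker, GWAS-variant proximity, VISTA proximity,
#' tooth-enhancer target and DEG status; bucketed points for the TSE count
#' ([tse_bucket_points()]); and module enrichment points ([module_points()]).
#' Scoring is a pure function of the evidence.
#'
#' @param evidence `data.frame` with one row per gene and the columns of
#'   `GeneEvidence` (see [evidence_columns()]); `marker_cell_types` is a
#'   comma-separated string.
#' @param module_scoring `"per_category"` or `"lump"`.
#' @param tiebreak `"tse"` (default) or `"ste"`: which enhancer count feeds
#'   the secondary ranking key.
#' @return `data.frame` of `ScoreBreakdown`s: `gene_id`, the eight `pts_*`
#'   components, `total`, `tiebreak`.
#' @export
score_genes <- function(evidence, module_scoring = c("per_category", "lump"),
                        tiebreak = c("tse", "ste")) {
  module_scoring <- match.arg(module_scoring)
  tiebreak <- match.arg(tiebreak)
  validate_evidence(evidence)
  types <- strsplit(ifelse(is.na(evidence$marker_cell_types), "",
                           evidence$marker_cell_types), ",", fixed = TRUE)
  types <- lapply(types, trimws)
  out <- data.frame(
    gene_id = evidence$gene_id,
    pts_marker = as.integer(evidence$is_marker),
    pts_dental_marker = vapply(types, dental_marker_points, integer(1)),
    pts_gwas = as.integer(evidence$near_gwas_variant),
    pts_tse_bucket = tse_bucket_points(evidence$n_tse),
    pts_module = vapply(seq_len(nrow(evidence)), function(i)
      module_points(list(enr_te_targets = evidence$enr_te_targets[i],
                         enr_dental_ontology = evidence$enr_dental_ontology[i],
                         enr_degs = evidence$enr_degs[i]),
                    scoring = module_scoring), integer(1)),
    pts_vista = as.integer(evidence$near_vista),
    pts_te_target = as.integer(evidence$is_te_target),
    pts_deg = as.integer(evidence$is_deg),
    stringsAsFactors = FALSE)
  out$total <- out$pts_marker + out$pts_dental_marker + out$pts_gwas +
    out$pts_tse_bucket + out$pts_module + out$pts_vista + out$pts_te_target +
    out$pts_deg
  out$tiebreak <- if (tiebreak == "tse") evidence$n_tse else evidence$n_ste
  out
}

#' @rdname score_genes
#' @param ev a single evidence row (one-row `data.frame` or named list;
#'   `marker_cell_types` may be a character vector).
#' @export
score_gene <- function(ev, module_scoring = c("per_category", "lump"),
                       tiebreak = c("tse", "ste")) {
  if (!is.data.frame(ev)) {
    if (length(ev$marker_cell_types) != 1)
      ev$marker_cell_types <- paste(ev$marker_cell_types, collapse = ",")
    ev <- as.data.frame(ev[evidence_columns()], stringsAsFactors = FALSE)
  }
  score_genes(ev, module_scoring = module_scoring, tiebreak = tiebreak)
}

#' Rank genes by composite score
#'
#' Removes genes belonging to `exclude_module` (the grey module of unassigned
#' genes by default), scores the rest, and orders by total descending, then
#' the tie-break enhancer count descending, then gene id ascending -- a fully
#' deterministic key.
#'
#' @param evidence evidence `data.frame` (one row per gene; duplicate ids are
#'   an error).
#' @param exclude_module module name to drop before scoring (`NULL` or `NA`
#'   to keep all).
#' @inheritParams score_genes
#' @return ranked `ScoreBreakdown` `data.frame` with a 1-based `rank` column
#'   plus the evidence's `module`, `n_tse` and `is_deg` columns for reporting.
#' @export
rank_genes <- function(evidence, exclude_module = "grey",
                       module_scoring = c("per_category", "lump"),
                       tiebreak = c("tse", "ste")) {
  if (anyDuplicated(evidence$gene_id))
    stop("duplicate gene_id: ", evidence$gene_id[duplicated(evidence$gene_id)][1])
  if (!is.null(exclude_module) && !is.na(exclude_module))
    evidence <- evidence[evidence$module != exclude_module, , drop = FALSE]
  scored <- score_genes(evidence, module_scoring = module_scoring,
                        tiebreak = tiebreak)
  scored$module <- evidence$module
  scored$n_tse <- evidence$n_tse
  scored$is_deg <- evidence$is_deg
  scored$marker_cell_types <- evidence$marker_cell_types
  o <- order(-scored$total, -scored$tiebreak, scored$gene_id)
  scored <- scored[o, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored[, c("rank", setdiff(names(scored), "rank"))]
}
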