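# End-to-end orchestration: one flat configuration names every input file and
# every tunable parameter; run_pipeline() executes extract -> specificity ->
# association -> proximity -> retention filters -> module flags -> evidence
# assembly -> scoring -> ranking, and can write all stage tables plus a
# machine-readable run manifest.

config_defaults <- function() {
  list(
    seg_target = NULL, seg_backgrounds = character(), genes = NULL,
    chrom_sizes = NULL, gwas = NULL, vista = NULL, markers = NULL, de = NULL,
    modules = NULL, ontology_genes = NULL,
    state_model = 18, strong_states = c(8, 9, 10),
    specificity_mode = "remove_whole", min_bp = 1,
    basal_up = 5000, basal_down = 1000, max_extension = 1e6,
    variant_window = 5e5, variant_measure = "span", vista_window = 1e6,
    lfc_min = 2, padj_max = 0.05, gwas_alpha = 5e-8, gwas_traits = character(),
    n_perm = 10000, seed = 1, alpha = 0.05,
    tiebreak = "tse", module_scoring = "per_category",
    exclude_module = "grey", te_target_kind = "strong")
}

#' Build a validated pipeline configuration
#'
#' A single flat key-value configuration: paths to all inputs plus every
#' tunable parameter with its default. Unknown keys are rejected; numeric
#' parameters are range-checked.
#'
#' @param ... configuration entries overriding the defaults (see
#'   `toothprior:::config_defaults()` for the full key list: input paths
#'   `seg_target`, `seg_backgrounds`, `genes`, `chrom_sizes`, `gwas`,
#'   `vista`, `markers`, `de`, `modules`, `ontology_genes`; parameters
#'   `strong_states`, `specificity_mode`, `min_bp`, GREAT basal/extension
#'   sizes, proximity windows, DE and GWAS thresholds, `n_perm`, `seed`,
#'   `alpha`, and the scoring options `tiebreak`, `module_scoring`,
#'   `exclude_module`, `te_target_kind`).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  extra <- list(...)
  unknown <- setdiff(names(extra), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(extra)] <- extra
  stopifnot(cfg$state_model %in% c(15, 18),
            all(cfg$strong_states >= 1 & cfg$strong_states <= cfg$state_model),
            cfg$specificity_mode %in% c("remove_whole", "trim"),
            cfg$min_bp >= 1, cfg$basal_up >= 0, cfg$basal_down >= 0,
            cfg$max_extension >= 0, cfg$variant_window >= 0,
            cfg$vista_window >= 0, cfg$variant_measure %in% c("span", "tss"),
            cfg$padj_max >= 0, cfg$padj_max <= 1,
            cfg$gwas_alpha > 0, cfg$gwas_alpha <= 1,
            cfg$n_perm >= 1, cfg$alpha > 0, cfg$alpha <= 1,
            cfg$tiebreak %in% c("tse", "ste"),
            cfg$module_scoring %in% c("per_category", "lump"),
            cfg$te_target_kind %in% c("strong", "tissue_specific"))
  structure(cfg, class = "PipelineConfig")
}

#' Configuration pointing at a written synthetic world
#'
#' @param dir directory produced by [write_world()].
#' @param ... configuration overrides passed to [pipeline_config()].
#' @return `PipelineConfig` whose input paths and planted parameters
#'   (windows, traits, significance threshold) match the world.
#' @export
world_config <- function(dir, ...) {
  f <- world_files(dir)
  segs <- sort(list.files(dir, pattern = "^segmentation_.*\\.bed$",
                          full.names = TRUE))
  target <- segs[grepl("segmentation_tooth\\.bed$", segs)]
  overrides <- list(...)
  base <- list(seg_target = target, seg_backgrounds = setdiff(segs, target),
               genes = unname(f["genes"]), chrom_sizes = unname(f["chrom_sizes"]),
               gwas = unname(f["gwas"]), vista = unname(f["vista"]),
               markers = unname(f["markers"]), de = unname(f["de"]),
               modules = unname(f["modules"]),
               ontology_genes = unname(f["ontology"]),
               gwas_traits = c("odontogenesis", "tooth eruption"))
  base[names(overrides)] <- overrides
  do.call(pipeline_config, base)
}

check_inputs <- function(cfg) {
  paths <- c(cfg$seg_target, cfg$seg_backgrounds, cfg$genes, cfg$chrom_sizes,
             cfg$gwas, cfg$vista, cfg$markers, cfg$de, cfg$modules,
             cfg$ontology_genes)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing))
    stop("input file(s) not found: ", paste(unlist(missing), collapse = ", "))
}

#' Run the full prioritization pipeline
#'
#' Executes every stage from segmentation input to the ranked candidate-locus
#' table. Fully deterministic given the configuration (the configured `seed`
#' drives the permutation tests).
#'
#' @param config `PipelineConfig` from [pipeline_config()] /
#'   [world_config()].
#' @param out_dir optional directory; when given, writes `ranked.tsv`,
#'   `evidence.tsv`, `enrichment.tsv`, `ste.bed`, `tse.bed` and
#'   `run_manifest.json` (configuration echo, input checksums, seed).
#' @return list with `ranked` (the prioritized table with full score
#'   decomposition), `evidence` (per-gene assembled evidence), `ste`/`tse`
#'   (`EnhancerSet`s), `links` (per-gene enhancer counts), `module_flags`
#'   (with per-test detail in its `"detail"` attribute), and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- config
  check_inputs(cfg)

  ## enhancer extraction
  target <- read_segmentation(cfg$seg_target, sample_id = "target",
                              state_model = cfg$state_model)
  ste <- extract_strong_enhancers(target, cfg$strong_states)
  backgrounds <- lapply(cfg$seg_backgrounds, function(p)
    extract_strong_enhancers(
      read_segmentation(p, sample_id = basename(p),
                        state_model = cfg$state_model), cfg$strong_states))
  tse <- tissue_specific_enhancers(ste, backgrounds,
                                   mode = cfg$specificity_mode,
                                   min_bp = cfg$min_bp)

  ## gene association
  genes <- read_gene_table(cfg$genes)
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  domains <- build_regulatory_domains(genes, basal_up = cfg$basal_up,
                                      basal_down = cfg$basal_down,
                                      max_extension = cfg$max_extension,
                                      chrom_sizes = sizes)
  links <- gene_enhancer_links(ste, tse, domains)

  ## proximity and retention filters
  variants <- filter_gwas_variants(read_gwas_table(cfg$gwas),
                                   alpha = cfg$gwas_alpha,
                                   traits = cfg$gwas_traits)
  gwas_genes <- genes_near_variants(genes, variants,
                                    window = cfg$variant_window,
                                    measure = cfg$variant_measure)
  vista_genes <- genes_near_intervals(genes, read_bed(cfg$vista),
                                      window = cfg$vista_window)
  deg_genes <- filter_de_genes(read_de_table(cfg$de),
                               lfc_min = cfg$lfc_min, padj_max = cfg$padj_max)

  ## module enrichment flags (excluded module is dropped from ranking anyway,
  ## so it is not tested)
  modules <- read_module_table(cfg$modules)
  markers <- read_marker_table(cfg$markers)
  ontology <- if (!is.null(cfg$ontology_genes)) readLines(cfg$ontology_genes)
              else character()
  universe <- modules$gene_id
  te_kind <- if (cfg$te_target_kind == "strong") "n_ste" else "n_tse"
  te_targets <- links$gene_id[links[[te_kind]] >= 1]
  tested <- setdiff(unique(modules$module), cfg$exclude_module)
  members <- split(modules$gene_id, modules$module)[tested]
  flags <- module_enrichment_flags(members, te_targets, ontology, deg_genes,
                                   universe, n_perm = cfg$n_perm,
                                   seed = cfg$seed, alpha = cfg$alpha)

  ## evidence assembly over the module-table genes
  mk <- split(markers$cell_type, markers$gene_id)
  link_row <- match(modules$gene_id, links$gene_id)
  flag_row <- match(modules$module, flags$module)
  evidence <- data.frame(
    gene_id = modules$gene_id, module = modules$module,
    is_marker = modules$gene_id %in% names(mk),
    marker_cell_types = vapply(modules$gene_id, function(g)
      paste(unique(mk[[g]]), collapse = ","), character(1), USE.NAMES = FALSE),
    near_gwas_variant = modules$gene_id %in% gwas_genes,
    n_tse = links$n_tse[link_row], n_ste = links$n_ste[link_row],
    enr_te_targets = !is.na(flag_row) & flags$enr_te_targets[flag_row],
    enr_dental_ontology = !is.na(flag_row) & flags$enr_dental_ontology[flag_row],
    enr_degs = !is.na(flag_row) & flags$enr_degs[flag_row],
    near_vista = modules$gene_id %in% vista_genes,
    is_deg = modules$gene_id %in% deg_genes,
    stringsAsFactors = FALSE)
  evidence$is_te_target <- evidence[[te_kind]] >= 1
  if (any(is.na(link_row)))
    stop("gene(s) in module table absent from gene table: ",
         paste(modules$gene_id[is.na(link_row)][1], collapse = ", "))

  ranked <- rank_genes(evidence, exclude_module = cfg$exclude_module,
                       module_scoring = cfg$module_scoring,
                       tiebreak = cfg$tiebreak)
  result <- list(ranked = ranked, evidence = evidence, ste = ste, tse = tse,
                 links = links, module_flags = flags, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(result$ranked, "ranked.tsv")
  wtsv(result$evidence, "evidence.tsv")
  wtsv(attr(result$module_flags, "detail"), "enrichment.tsv")
  write_bed(result$ste$intervals, file.path(out_dir, "ste.bed"))
  write_bed(result$tse$intervals, file.path(out_dir, "tse.bed"))
  cfg <- result$config
  inputs <- unlist(cfg[c("seg_target", "seg_backgrounds", "genes",
                         "chrom_sizes", "gwas", "vista", "markers", "de",
                         "modules", "ontology_genes")])
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
    inputs = lapply(stats::setNames(as.list(inputs), basename(inputs)),
                    function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
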