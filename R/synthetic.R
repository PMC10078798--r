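# Seeded generator of a toy multi-tissue genomic world with planted
# structure. The world mirrors the statistical shape of the real inputs --
# strong-enhancer states 8-10 in a segmentation, tissue specificity against
# background tissues, variant/VISTA proximity windows, co-expression modules
# with enrichment structure -- at a scale where the whole pipeline plus
# 10,000-permutation enrichment runs in seconds.
#
# Two layout rules make ground truth computable by arithmetic, before any
# pipeline code runs:
#   * genes sit 2.5 Mb apart on 80 Mb chromosomes, so regulatory domains
#     (basal +/- 1 Mb), 500 kbp variant windows and 1 Mb VISTA windows of
#     different genes never interleave: every planted element belongs to
#     exactly one gene;
#   * each non-grey module is either a subset of or disjoint from each
#     enrichment category, so the truth value of every permutation-derived
#     module flag is determined by construction.

#' Default planting parameters for [generate_world()]
#'
#' Five modules are planted. `red` genes are high-priority (many
#' tissue-specific enhancers, dental markers, DEGs; module enriched for all
#' three categories), `blue` genes carry enhancers without differential
#' expression, `yellow` genes are DEGs without enhancers, `green` genes are
#' null, and `grey` is the unassigned module exercised by the ranking
#' exclusion.
#'
#' @return list of planting parameters; see source for fields.
#' @export
default_plant_spec <- function() {
  list(
    modules = data.frame(
      module = c("red", "blue", "yellow", "green", "grey"),
      frac = c(0.17, 0.20, 0.20, 0.20, 0.23),
      enr_te = c(TRUE, TRUE, FALSE, FALSE, FALSE),
      enr_onto = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      enr_deg = c(TRUE, FALSE, TRUE, FALSE, FALSE),
      tse_min = c(5, 0, 0, 0, 0), tse_max = c(12, 4, 0, 0, 8),
      shared_min = c(0, 0, 0, 0, 0), shared_max = c(3, 2, 0, 0, 2),
      p_marker = c(1.0, 0.7, 0.6, 0.5, 0.5),
      p_dental = c(1.0, 0.3, 0.5, 0.4, 0.5),
      p_gwas = c(0.9, 0.4, 0.4, 0.2, 0.3),
      p_vista = c(0.8, 0.3, 0.3, 0.2, 0.3),
      stringsAsFactors = FALSE),
    enhancer_width = 600, enhancer_stride = 1200, max_slots = 15,
    gene_spacing = 2.5e6, first_gene_at = 2e6, n_chroms = 2,
    gene_len_min = 5000, gene_len_max = 20000,
    variant_window = 5e5, vista_window = 1e6,
    gwas_alpha = 5e-8, traits = c("odontogenesis", "tooth eruption"),
    strong_states = c(8, 9, 10))
}

state_label <- function(state) {
  nm <- c("1" = "TssA", "2" = "TssFlnk", "4" = "Tx", "8" = "EnhG1",
          "9" = "EnhA1", "10" = "EnhA2", "14" = "ReprPC")
  paste0(state, "_", ifelse(as.character(state) %in% names(nm),
                            nm[as.character(state)], "Other"))
}

# Truth-side bucket arithmetic, written out by hand as part of the
# construction (the pipeline's tse_bucket_points is never consulted here).
truth_bucket <- function(n) {
  vapply(n, function(x) {
    if (x == 0) 0L else if (x <= 2) 1L else if (x <= 4) 2L
    else if (x <= 6) 3L else 4L
  }, integer(1))
}

#' Generate a synthetic multi-tissue world
#'
#' Builds gene models, one target-tissue segmentation plus background-tissue
#' segmentations with planted strong-enhancer states, GWAS-style variants at
#' controlled distances (inside the gene, at the window boundary, one base
#' beyond it, far decoys, sub-threshold and off-trait decoys), VISTA-style
#' elements, marker/DE/module tables -- and records the ground-truth evidence
#' and score of every gene by construction.
#'
#' @param seed integer seed; identical seeds give identical worlds.
#' @param n_genes number of genes (>= 20 so every module is populated).
#' @param n_tissues total tissues: 1 target plus `n_tissues - 1` backgrounds.
#' @param plant_spec planting parameters, see [default_plant_spec()].
#' @return A `SyntheticWorld` list: `seed`, `chrom_sizes`, `genes`,
#'   `segmentations` (list of `SegmentationTrack`), `variants`,
#'   `vista_elements`, `marker_table`, `de_table`, `module_table`,
#'   `ontology_genes`, `params`, `pins` (the boundary-pinned gene ids) and
#'   `truth` (`evidence`, `scores`, `ranking`, `tse_intervals`,
#'   `ste_intervals`).
#' @export
generate_world <- function(seed, n_genes = 60, n_tissues = 4,
                           plant_spec = default_plant_spec()) {
  stopifnot(n_genes >= 20, n_tissues >= 2)
  ps <- plant_spec
  if (any(ps$modules$tse_max + ps$modules$shared_max > ps$max_slots))
    stop("infeasible plant_spec: more enhancers than available slots")
  with_local_seed(seed, build_world(seed, n_genes, n_tissues, ps))
}

build_world <- function(seed, n_genes, n_tissues, ps) {
  mods <- ps$modules
  ## ---- gene models -------------------------------------------------------
  per_chrom <- ceiling(n_genes / ps$n_chroms)
  chrom_len <- ps$first_gene_at + per_chrom * ps$gene_spacing + 5e6
  chroms <- paste0("chr", seq_len(ps$n_chroms))
  chrom_sizes <- stats::setNames(rep(chrom_len, ps$n_chroms), chroms)
  idx <- seq_len(n_genes) - 1
  gchrom <- chroms[idx %/% per_chrom + 1]
  gstart <- ps$first_gene_at + (idx %% per_chrom) * ps$gene_spacing
  glen <- sample(ps$gene_len_min:ps$gene_len_max, n_genes, replace = TRUE)
  strand <- rep_len(c("+", "-"), n_genes)
  genes <- gene_records(data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    symbol = sprintf("Tsyn%03d", seq_len(n_genes)),
    chrom = gchrom, start = gstart, end = gstart + glen, strand = strand,
    ortholog_id = sprintf("TSYN%03d", seq_len(n_genes)),
    stringsAsFactors = FALSE))

  ## ---- module assignment -------------------------------------------------
  counts <- diff(c(0, round(cumsum(mods$frac) * n_genes)))
  counts[length(counts)] <- n_genes - sum(counts[-length(counts)])
  module <- rep(mods$module, counts)[sample.int(n_genes)]
  mrow <- match(module, mods$module)

  ## ---- per-gene evidence plants ------------------------------------------
  n_tse <- mapply(function(lo, hi) if (hi > lo) sample(lo:hi, 1) else lo,
                  mods$tse_min[mrow], mods$tse_max[mrow])
  n_shared <- mapply(function(lo, hi) if (hi > lo) sample(lo:hi, 1) else lo,
                     mods$shared_min[mrow], mods$shared_max[mrow])
  # a te-enriched module means every member is an enhancer target
  need_te <- mods$enr_te[mrow] & (n_tse + n_shared) == 0
  n_shared[need_te] <- 1
  is_marker <- stats::runif(n_genes) < mods$p_marker[mrow]
  is_dental <- is_marker & (stats::runif(n_genes) < mods$p_dental[mrow])
  near_gwas <- stats::runif(n_genes) < mods$p_gwas[mrow]
  near_vista <- stats::runif(n_genes) < mods$p_vista[mrow]
  is_deg <- mods$enr_deg[mrow]

  # boundary pins: one gene gains a variant at exactly the window (inside),
  # one keeps a variant one base beyond it (outside); same for VISTA
  pin <- list()
  pick_unflagged <- function(flag, used) {
    cand <- setdiff(which(!flag), used)
    if (length(cand) < 2) cand <- setdiff(seq_along(flag), used)
    cand[1:2]
  }
  vp <- pick_unflagged(near_gwas, integer())
  pin$gwas_at_window <- genes$gene_id[vp[1]]; near_gwas[vp[1]] <- TRUE
  pin$gwas_beyond_window <- genes$gene_id[vp[2]]; near_gwas[vp[2]] <- FALSE
  ep <- pick_unflagged(near_vista, vp)
  pin$vista_at_window <- genes$gene_id[ep[1]]; near_vista[ep[1]] <- TRUE
  pin$vista_beyond_window <- genes$gene_id[ep[2]]; near_vista[ep[2]] <- FALSE

  ## ---- enhancer slots and segmentation tracks ----------------------------
  slot_iv <- function(i, j) {
    s <- genes$tss[i] + 3000 + j * ps$enhancer_stride
    c(s, s + ps$enhancer_width)
  }
  tse_list <- list(); shared_list <- list()
  for (i in seq_len(n_genes)) {
    tot <- n_tse[i] + n_shared[i]
    if (tot == 0) next
    coords <- t(vapply(seq_len(tot) - 1, function(j) slot_iv(i, j), numeric(2)))
    states <- sample(ps$strong_states, tot, replace = TRUE)
    df <- data.frame(chrom = genes$chrom[i], start = coords[, 1],
                     end = coords[, 2], label = state_label(states),
                     strand = ".", gene_id = genes$gene_id[i],
                     stringsAsFactors = FALSE)
    if (n_tse[i] > 0) tse_list[[length(tse_list) + 1]] <- df[seq_len(n_tse[i]), ]
    if (n_shared[i] > 0)
      shared_list[[length(shared_list) + 1]] <- df[n_tse[i] + seq_len(n_shared[i]), ]
  }
  bind <- function(lst) if (length(lst)) do.call(rbind, lst) else
    cbind(empty_intervals(), gene_id = character())
  tse_segs <- bind(tse_list); shared_segs <- bind(shared_list)

  filler <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    data.frame(chrom = genes$chrom[i],
               start = c(genes$tss[i] - 30000, genes$tss[i] + 40000),
               end = c(genes$tss[i] - 25000, genes$tss[i] + 42000),
               label = c(state_label(14), state_label(1)),
               strand = ".", stringsAsFactors = FALSE)
  }))
  seg_cols <- c("chrom", "start", "end", "label", "strand")
  target_track <- segmentation_track(
    "tooth", rbind(tse_segs[seg_cols], shared_segs[seg_cols], filler))
  desert_start <- chrom_len - 3e6
  bg_names <- paste0("background", seq_len(n_tissues - 1))
  segmentations <- c(list(target_track), lapply(seq_along(bg_names), function(b) {
    own <- do.call(rbind, lapply(chroms, function(ch) {
      s <- desert_start + b * 60000 + (0:7) * 2000
      data.frame(chrom = ch, start = s, end = s + 800,
                 label = state_label(sample(ps$strong_states, 8, replace = TRUE)),
                 strand = ".", stringsAsFactors = FALSE)
    }))
    segmentation_track(bg_names[b], rbind(shared_segs[seg_cols], own, filler))
  }))
  names(segmentations) <- c("tooth", bg_names)

  ## ---- variants ----------------------------------------------------------
  rs <- local({ i <- 0; function() { i <<- i + 1; sprintf("rs%06d", i) } })
  vrows <- list()
  add_variant <- function(chrom, pos, p, trait)
    vrows[[length(vrows) + 1]] <<- data.frame(
      variant_id = rs(), chrom = chrom, pos = pos, pvalue = p, trait = trait,
      stringsAsFactors = FALSE)
  sig_p <- function() ps$gwas_alpha * 10^-stats::runif(1, 0, 8)
  a_trait <- function() sample(ps$traits, 1)
  for (i in which(near_gwas)) {
    d <- if (genes$gene_id[i] == pin$gwas_at_window) ps$variant_window
         else sample(c(0, sample.int(ps$variant_window, 1)), 1)
    pos <- if (d == 0) floor((genes$start[i] + genes$end[i]) / 2)
           else genes$end[i] - 1 + d
    p <- if (genes$gene_id[i] == pin$gwas_at_window) ps$gwas_alpha else sig_p()
    add_variant(genes$chrom[i], pos, p, a_trait())
  }
  i_out <- match(pin$gwas_beyond_window, genes$gene_id)
  add_variant(genes$chrom[i_out], genes$end[i_out] - 1 + ps$variant_window + 1,
              sig_p(), a_trait())
  for (i in sample(which(!near_gwas), min(6, sum(!near_gwas)))) {
    if (genes$gene_id[i] == pin$gwas_beyond_window) next
    pos <- genes$end[i] - 1 + sample.int(ps$variant_window, 1)
    if (stats::runif(1) < 0.5) add_variant(genes$chrom[i], pos, 1e-6, a_trait())
    else add_variant(genes$chrom[i], pos, sig_p(), "body height")
  }
  for (ch in chroms)  # far decoys, beyond any window
    add_variant(ch, desert_start + sample.int(1e6, 1), sig_p(), a_trait())
  variants <- do.call(rbind, vrows)

  ## ---- VISTA elements ----------------------------------------------------
  erows <- list()
  for (i in which(near_vista)) {
    d <- if (genes$gene_id[i] == pin$vista_at_window) ps$vista_window
         else sample(c(0, sample.int(ps$vista_window, 1)), 1)
    s <- if (d == 0) genes$start[i] else genes$end[i] - 1 + d
    erows[[length(erows) + 1]] <- data.frame(
      chrom = genes$chrom[i], start = s, end = s + 1500,
      label = sprintf("vista_%s", genes$gene_id[i]), strand = ".",
      stringsAsFactors = FALSE)
  }
  i_out <- match(pin$vista_beyond_window, genes$gene_id)
  erows[[length(erows) + 1]] <- data.frame(
    chrom = genes$chrom[i_out],
    start = genes$end[i_out] - 1 + ps$vista_window + 1,
    end = genes$end[i_out] - 1 + ps$vista_window + 1501,
    label = "vista_beyond", strand = ".", stringsAsFactors = FALSE)
  erows[[length(erows) + 1]] <- data.frame(
    chrom = chroms[1], start = desert_start + 2e6, end = desert_start + 2e6 + 1500,
    label = "vista_desert", strand = ".", stringsAsFactors = FALSE)
  vista <- do.call(rbind, erows)

  ## ---- marker / DE / module tables ---------------------------------------
  dental <- dental_cell_types()
  other_types <- c("Bone Progenitor Cells", "Endothelium", "Immune Cells",
                   "Glia", "Muscle")
  marker_types <- vector("list", n_genes)
  mrows <- list()
  for (i in which(is_marker)) {
    tys <- if (is_dental[i]) unique(c(sample(dental, sample(1:2, 1)),
                                      if (stats::runif(1) < 0.3) sample(other_types, 1)))
           else sample(other_types, sample(1:2, 1))
    marker_types[[i]] <- tys
    mrows[[length(mrows) + 1]] <- data.frame(
      gene_id = genes$gene_id[i], cell_type = tys,
      log2fc = round(stats::runif(length(tys), 1, 3), 3),
      padj = signif(10^-stats::runif(length(tys), 5, 50), 3),
      stringsAsFactors = FALSE)
  }
  marker_table <- if (length(mrows)) do.call(rbind, mrows) else
    data.frame(gene_id = character(), cell_type = character(),
               log2fc = numeric(), padj = numeric(), stringsAsFactors = FALSE)

  de_lfc <- ifelse(is_deg, stats::runif(n_genes, 2.5, 6),
                   stats::runif(n_genes, -2, 1.5))
  de_padj <- ifelse(is_deg, 10^-stats::runif(n_genes, 4, 20),
                    stats::runif(n_genes, 0.2, 0.9))
  # threshold edge cases: strictly-greater fold change, inclusive adjusted p
  edge_out <- which(!is_deg)[1]; de_lfc[edge_out] <- 2.0; de_padj[edge_out] <- 0.01
  edge_in <- which(is_deg)[1]; de_lfc[edge_in] <- 3.0; de_padj[edge_in] <- 0.05
  de_table <- data.frame(gene_id = genes$gene_id, log2fc = round(de_lfc, 4),
                         padj = signif(de_padj, 6), stringsAsFactors = FALSE)
  module_table <- data.frame(gene_id = genes$gene_id, module = module,
                             stringsAsFactors = FALSE)
  ontology_genes <- genes$gene_id[module == "red"]

  ## ---- ground truth, by construction -------------------------------------
  n_ste <- n_tse + n_shared
  evidence <- data.frame(
    gene_id = genes$gene_id, module = module, is_marker = is_marker,
    marker_cell_types = vapply(marker_types, function(t)
      if (is.null(t)) "" else paste(t, collapse = ","), character(1)),
    near_gwas_variant = near_gwas, n_tse = as.integer(n_tse),
    n_ste = as.integer(n_ste),
    enr_te_targets = mods$enr_te[mrow] & module != "grey",
    enr_dental_ontology = mods$enr_onto[mrow] & module != "grey",
    enr_degs = mods$enr_deg[mrow] & module != "grey",
    near_vista = near_vista, is_te_target = n_ste >= 1, is_deg = is_deg,
    stringsAsFactors = FALSE)
  pts_dental <- as.integer(vapply(marker_types, function(t)
    length(intersect(t, dental)) > 0, logical(1)))
  scores <- data.frame(
    gene_id = genes$gene_id,
    pts_marker = as.integer(is_marker), pts_dental_marker = pts_dental,
    pts_gwas = as.integer(near_gwas), pts_tse_bucket = truth_bucket(n_tse),
    pts_module = as.integer(evidence$enr_te_targets) +
      as.integer(evidence$enr_dental_ontology) + as.integer(evidence$enr_degs),
    pts_vista = as.integer(near_vista),
    pts_te_target = as.integer(n_ste >= 1), pts_deg = as.integer(is_deg),
    stringsAsFactors = FALSE)
  scores$total <- rowSums(scores[-1])
  scores$n_tse <- as.integer(n_tse)
  keep <- module != "grey"
  ranking <- scores[keep, ][order(-scores$total[keep], -scores$n_tse[keep],
                                  scores$gene_id[keep]), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL

  sort_iv <- function(df) {
    df <- df[order(df$chrom, df$start), c(seg_cols, "gene_id"), drop = FALSE]
    rownames(df) <- NULL; df
  }
  structure(list(
    seed = seed, chrom_sizes = chrom_sizes, genes = genes,
    segmentations = segmentations, variants = variants, vista_elements = vista,
    marker_table = marker_table, de_table = de_table,
    module_table = module_table, ontology_genes = ontology_genes,
    params = ps[c("variant_window", "vista_window", "gwas_alpha", "traits",
                  "strong_states")],
    pins = pin,
    truth = list(evidence = evidence, scores = scores, ranking = ranking,
                 tse_intervals = sort_iv(tse_segs),
                 ste_intervals = sort_iv(rbind(tse_segs, shared_segs)))),
    class = "SyntheticWorld")
}

#' @export
print.SyntheticWorld <- function(x, ...) {
  cat(sprintf("SyntheticWorld (seed %d): %d genes on %d chromosomes, %d tissues, %d variants\n",
              x$seed, nrow(x$genes), length(x$chrom_sizes),
              length(x$segmentations), nrow(x$variants)))
  invisible(x)
}

#' File names written by [write_world()]
#' @param dir world directory.
#' @return named character vector of paths.
#' @export
world_files <- function(dir) {
  c(chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    genes = file.path(dir, "genes.tsv"),
    gwas = file.path(dir, "gwas_variants.tsv"),
    vista = file.path(dir, "vista_elements.bed"),
    markers = file.path(dir, "markers.tsv"),
    de = file.path(dir, "de_genes.tsv"),
    modules = file.path(dir, "modules.tsv"),
    ontology = file.path(dir, "ontology_genes.txt"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "manifest.json"))
}

#' Serialize a synthetic world to its on-disk input formats
#'
#' Writes one dense segmentation BED per tissue, the gene/variant/marker/DE/
#' module tables, the VISTA BED, chromosome sizes, the ground-truth JSON, and
#' a manifest recording the seed and an md5 checksum of every file.
#'
#' @param world `SyntheticWorld`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths (the manifest last), invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "SyntheticWorld"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- world_files(dir)
  wtsv <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  # chrom_sizes written headerless for read_chrom_sizes
  writeLines(paste(names(world$chrom_sizes),
                   format(world$chrom_sizes, scientific = FALSE, trim = TRUE),
                   sep = "\t"), f["chrom_sizes"])
  gcols <- c("gene_id", "symbol", "chrom", "start", "end", "strand", "ortholog_id")
  wtsv(world$genes[gcols], f["genes"])
  seg_paths <- character()
  for (nm in names(world$segmentations)) {
    p <- file.path(dir, sprintf("segmentation_%s.bed", nm))
    write_bed(world$segmentations[[nm]]$segments, p)
    seg_paths[paste0("segmentation_", nm)] <- p
  }
  gw <- world$variants
  gw_out <- data.frame(SNPS = gw$variant_id, CHR_ID = gw$chrom,
                       CHR_POS = format(gw$pos + 1, scientific = FALSE, trim = TRUE),
                       `P-VALUE` = sprintf("%.16e", gw$pvalue),
                       MAPPED_TRAIT = gw$trait, check.names = FALSE,
                       stringsAsFactors = FALSE)
  wtsv(gw_out, f["gwas"])
  write_bed(world$vista_elements, f["vista"])
  wtsv(world$marker_table, f["markers"])
  wtsv(world$de_table, f["de"])
  wtsv(world$module_table, f["modules"])
  writeLines(world$ontology_genes, f["ontology"])
  jsonlite::write_json(world$truth, f["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c(f[setdiff(names(f), c("manifest"))], seg_paths)
  manifest <- list(seed = world$seed,
                   files = lapply(stats::setNames(as.list(files), basename(files)),
                                  function(p) list(path = basename(p),
                                                   md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, f["manifest"], auto_unbox = TRUE)
  invisible(c(files, manifest = unname(f["manifest"])))
}
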