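base_evidence <- function(gene_id = "g1", module = "red", is_marker = FALSE,
                          marker_cell_types = "", near_gwas_variant = FALSE,
                          n_tse = 0L, n_ste = 0L, enr_te_targets = FALSE,
                          enr_dental_ontology = FALSE, enr_degs = FALSE,
                          near_vista = FALSE, is_te_target = FALSE,
                          is_deg = FALSE) {
  data.frame(gene_id = gene_id, module = module, is_marker = is_marker,
             marker_cell_types = marker_cell_types,
             near_gwas_variant = near_gwas_variant, n_tse = n_tse,
             n_ste = n_ste, enr_te_targets = enr_te_targets,
             enr_dental_ontology = enr_dental_ontology, enr_degs = enr_degs,
             near_vista = near_vista, is_te_target = is_te_target,
             is_deg = is_deg, stringsAsFactors = FALSE)
}

maximal_evidence <- function(gene_id = "g1", n_tse = 8L)
  base_evidence(gene_id, is_marker = TRUE, marker_cell_types = "Mesenchyme",
                near_gwas_variant = TRUE, n_tse = n_tse, n_ste = n_tse,
                enr_te_targets = TRUE, enr_dental_ontology = TRUE,
                enr_degs = TRUE, near_vista = TRUE, is_te_target = TRUE,
                is_deg = TRUE)

test_that("TSE bucket follows the printed piecewise table", {
  expect_equal(tse_bucket_points(c(0, 1, 2, 3, 4, 5, 6, 7, 10, 100)),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L))
  expect_error(tse_bucket_points(-1), "non-negative")
})

test_that("dental-marker point requires one of the four dental cell types", {
  expect_equal(dental_marker_points("Mesenchyme"), 1L)
  expect_equal(dental_marker_points(c("Bone Progenitor Cells", "Glia")), 0L)
  expect_equal(dental_marker_points(character()), 0L)
  expect_equal(dental_marker_points(c("Glia", "Enamel Knot")), 1L)
})

test_that("module points count true flags, with a lump-sum option", {
  f <- function(a, b, c) list(enr_te_targets = a, enr_dental_ontology = b,
                              enr_degs = c)
  expect_equal(module_points(f(FALSE, FALSE, FALSE)), 0L)
  expect_equal(module_points(f(TRUE, TRUE, TRUE)), 3L)
  expect_equal(module_points(f(FALSE, TRUE, FALSE)), 1L)
  expect_equal(module_points(f(TRUE, TRUE, FALSE), scoring = "lump"), 1L)
})

test_that("score decomposition sums to the total, 0 through 13", {
  s0 <- score_genes(base_evidence())
  expect_equal(s0$total, 0L)
  s13 <- score_genes(maximal_evidence())
  expect_equal(s13$total, 13L)
  comp <- c("pts_marker", "pts_dental_marker", "pts_gwas", "pts_tse_bucket",
            "pts_module", "pts_vista", "pts_te_target", "pts_deg")
  expect_equal(rowSums(s13[comp]), c(13), ignore_attr = TRUE)
})

test_that("a top-row evidence pattern can reach its printed total", {
  # marker + dental marker (Mesenchyme) + DEG + 10 TSEs give base 7; some
  # assignment of the unprinted components reaches the printed total of 11
  ev <- base_evidence("Runx2", is_marker = TRUE,
                      marker_cell_types = "Mesenchyme", n_tse = 10L,
                      n_ste = 10L, is_deg = TRUE)
  expect_equal(score_genes(ev)$total, 7L)
  ev$near_gwas_variant <- TRUE; ev$enr_te_targets <- TRUE
  ev$enr_degs <- TRUE; ev$near_vista <- TRUE
  expect_equal(score_genes(ev)$total, 11L)
})

test_that("scoring is pure and monotone in every component", {
  ev <- base_evidence(n_tse = 3L, n_ste = 4L)
  expect_identical(score_genes(ev), score_genes(ev))
  bools <- c("is_marker", "near_gwas_variant", "enr_te_targets",
             "enr_dental_ontology", "enr_degs", "near_vista", "is_te_target",
             "is_deg")
  for (b in bools) {
    up <- ev; up[[b]] <- TRUE
    if (b == "is_marker") up$marker_cell_types <- "Glia"
    expect_gte(score_genes(up)$total, score_genes(ev)$total)
  }
  up <- ev; up$n_tse <- 7L
  expect_gt(score_genes(up)$total, score_genes(ev)$total)
})

test_that("random evidence matches the spreadsheet oracle", {
  withr::local_seed(31)
  for (i in 1:50) {
    dental <- runif(1) < 0.5
    marker <- dental || runif(1) < 0.5
    n_flags <- sample(0:3, 1)
    flags <- c(rep(TRUE, n_flags), rep(FALSE, 3 - n_flags))[sample.int(3)]
    n_tse <- sample(0:12, 1)
    ev <- base_evidence(is_marker = marker,
                        marker_cell_types = if (dental) "Epithelium,Glia"
                                            else if (marker) "Glia" else "",
                        near_gwas_variant = runif(1) < 0.5,
                        n_tse = n_tse, n_ste = n_tse,
                        enr_te_targets = flags[1],
                        enr_dental_ontology = flags[2], enr_degs = flags[3],
                        near_vista = runif(1) < 0.5,
                        is_te_target = runif(1) < 0.5,
                        is_deg = runif(1) < 0.5)
    want <- oracle_score_row(marker, dental, ev$near_gwas_variant, n_tse,
                             n_flags, ev$near_vista, ev$is_te_target,
                             ev$is_deg)
    expect_equal(score_genes(ev)$total, as.integer(want))
  }
})

test_that("ranking orders by total, then TSE count, then gene id, after grey exclusion", {
  ev <- rbind(maximal_evidence("b_gene", n_tse = 10L),
              maximal_evidence("a_gene", n_tse = 10L),
              base_evidence("mid", is_marker = TRUE,
                            marker_cell_types = "Glia", n_tse = 6L, n_ste = 6L),
              base_evidence("low"),
              base_evidence("hidden", module = "grey", n_tse = 12L))
  ev$near_gwas_variant[3] <- TRUE
  r <- rank_genes(ev)
  expect_equal(r$gene_id, c("a_gene", "b_gene", "mid", "low"))
  expect_equal(r$rank, 1:4)
  expect_false("hidden" %in% r$gene_id)
  # tie on total broken by higher TSE count
  ev2 <- rbind(maximal_evidence("x", n_tse = 10L), maximal_evidence("y", n_tse = 7L))
  expect_equal(rank_genes(ev2)$gene_id, c("x", "y"))
  # removing the exclusion preserves relative order of retained genes
  r_all <- rank_genes(ev, exclude_module = NA)
  expect_equal(setdiff(r_all$gene_id, "hidden"), r$gene_id)
  expect_error(rank_genes(rbind(ev, ev[1, ])), "duplicate gene_id")
})

test_that("evidence validation catches inconsistent marker fields", {
  ev <- base_evidence(marker_cell_types = "Mesenchyme")  # not flagged marker
  expect_error(score_genes(ev), "not flagged as marker")
  expect_error(score_genes(base_evidence()[, -3]), "missing column")
})
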