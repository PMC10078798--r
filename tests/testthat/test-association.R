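test_that("basal-plus-extension domains follow the stated arithmetic", {
  sizes <- c(chrZ = 1e7)
  g <- gene_fixture("g1", "chrZ", 2e6, 2e6 + 10000)
  d <- build_regulatory_domains(g, chrom_sizes = sizes)
  expect_equal(d$basal_start, 1995000)
  expect_equal(d$basal_end, 2001000)
  expect_equal(d$ext_start, 995000)
  expect_equal(d$ext_end, 3001000)

  # upstream extension of the second gene stops at the first gene's basal edge
  g2 <- gene_fixture(c("g1", "g2"), "chrZ", c(1e6, 1.01e6), c(1e6, 1.01e6) + 5000)
  d2 <- build_regulatory_domains(g2, chrom_sizes = sizes)
  expect_equal(d2$ext_start[2], 1001000)
  expect_equal(d2$ext_end[1], 1005000)

  # clipping at the chromosome boundary
  g3 <- gene_fixture("g1", "chrZ", 500, 1500)
  d3 <- build_regulatory_domains(g3, chrom_sizes = sizes)
  expect_equal(d3$basal_start, 0)
  expect_equal(d3$ext_start, 0)

  expect_error(build_regulatory_domains(g, chrom_sizes = c(chrY = 1e7)),
               "missing from chrom_sizes")

  # minus-strand basal window is strand-oriented around the TSS
  gm <- gene_fixture("g1", "chrZ", 2e6, 2e6 + 10000, strand = "-")
  dm <- build_regulatory_domains(gm, chrom_sizes = sizes)
  expect_equal(dm$basal_end - dm$basal_start, 6000)
  expect_true(dm$basal_start <= gm$tss && gm$tss < dm$basal_end)

  # with no extension allowed, extended == basal
  d0 <- build_regulatory_domains(g2, max_extension = 0, chrom_sizes = sizes)
  expect_equal(d0$ext_start, d0$basal_start)
  expect_equal(d0$ext_end, d0$basal_end)
})

test_that("genes with identical TSS do not truncate each other", {
  sizes <- c(chrZ = 1e7)
  g <- gene_fixture(c("a", "b"), "chrZ", c(2e6, 2e6), c(2e6 + 5000, 2e6 + 8000))
  d <- build_regulatory_domains(g, chrom_sizes = sizes)
  expect_equal(d$ext_start, rep(995000, 2))
  expect_equal(d$ext_end, rep(3001000, 2))
})

test_that("enhancer assignment multi-assigns and matches the all-pairs scan", {
  sizes <- c(chrZ = 1e7)
  g <- gene_fixture(c("a", "b"), "chrZ", c(2e6, 2.2e6), c(2e6, 2.2e6) + 5000)
  d <- build_regulatory_domains(g, chrom_sizes = sizes)
  inside_one <- genomic_intervals("chrZ", 1999000, 1999500)
  res <- assign_enhancers_to_genes(inside_one, d)
  expect_equal(res$counts$n[res$counts$gene_id == "a"], 1L)
  # overlapping extended domains: both genes hit
  between <- genomic_intervals("chrZ", 2100000, 2100500)
  res <- assign_enhancers_to_genes(between, d)
  expect_equal(res$counts$n, c(1L, 1L))
  expect_equal(sort(res$links$gene_id), c("a", "b"))

  withr::local_seed(23)
  for (i in 1:40) {
    n_genes <- 5
    gs <- gene_fixture(paste0("g", 1:n_genes), "chrZ",
                       start <- sort(sample.int(9e6, n_genes)), start + 5000,
                       strand = sample(c("+", "-"), n_genes, replace = TRUE))
    dom <- build_regulatory_domains(gs, chrom_sizes = sizes)
    ivs <- random_intervals(50, chroms = "chrZ", len = 1e7, max_w = 5000)
    got <- assign_enhancers_to_genes(ivs, dom)
    expect_equal(got$counts$n, as.integer(oracle_assign_counts(ivs, dom)))
    expect_equal(nrow(got$links), sum(oracle_assign_counts(ivs, dom)))
  }
})

test_that("variant proximity uses an inclusive window to the gene span", {
  g <- gene_fixture("g1", "chr1", 1e6, 1e6 + 10000)
  v <- function(pos, chrom = "chr1")
    data.frame(variant_id = "rs1", chrom = chrom, pos = pos, pvalue = 1e-9,
               trait = "t", stringsAsFactors = FALSE)
  expect_equal(genes_near_variants(g, v(1e6 + 500)), "g1")        # inside
  end_base <- 1e6 + 10000 - 1
  expect_equal(genes_near_variants(g, v(end_base + 500000)), "g1") # at window
  expect_equal(genes_near_variants(g, v(end_base + 500001)), character(0))
  expect_equal(genes_near_variants(g, v(1e6 + 500, chrom = "chr2")), character(0))
  # widening the window is monotone
  expect_equal(genes_near_variants(g, v(end_base + 500001), window = 500001), "g1")
  # TSS measure differs from span measure for a variant inside the body
  expect_equal(genes_near_variants(g, v(1e6 + 9000), window = 100, measure = "tss"),
               character(0))
})

test_that("interval proximity mirrors variant proximity with span distance", {
  g <- gene_fixture("g1", "chr1", 1e6, 1e6 + 10000)
  e <- function(s, w = 1500) genomic_intervals("chr1", s, s + w)
  expect_equal(genes_near_intervals(g, e(1e6 + 100)), "g1")
  end_base <- 1e6 + 10000 - 1
  expect_equal(genes_near_intervals(g, e(end_base + 1e6)), "g1")
  expect_equal(genes_near_intervals(g, e(end_base + 1e6 + 1)), character(0))
  expect_equal(genes_near_intervals(g, e(1e6)[0, ]), character(0))
})

test_that("GWAS retention is inclusive at 5e-8, trait-aware, deduplicated", {
  v <- data.frame(variant_id = c("rs1", "rs2", "rs1", "rs3", "rs3"),
                  chrom = "chr1", pos = c(10, 20, 10, 30, 40),
                  pvalue = c(5e-8, 6e-8, 5e-8, 1e-10, 1e-10),
                  trait = c("odontogenesis", "odontogenesis", "odontogenesis",
                            "height", "odontogenesis"),
                  stringsAsFactors = FALSE)
  got <- filter_gwas_variants(v)
  expect_equal(sort(unique(got$variant_id)), c("rs1", "rs3"))
  expect_equal(nrow(got), 3)  # rs1 deduplicated, rs3 kept at both positions
  got <- filter_gwas_variants(v, traits = "odontogenesis")
  expect_equal(sort(got$variant_id), c("rs1", "rs3"))
  expect_equal(nrow(got), 2)
})

test_that("DE retention is strict on fold change, inclusive on adjusted p", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(2.0, 3.1, 2.5, 2.5),
                   padj = c(0.01, 0.05, 0.051, 0.001),
                   stringsAsFactors = FALSE)
  expect_equal(sort(filter_de_genes(de)), c("b", "d"))
  expect_equal(filter_de_genes(de[0, ]), character(0))
  expect_error(filter_de_genes(de[, 1:2]), "missing column")
  bad <- de; bad$padj[1] <- 1.5
  expect_error(filter_de_genes(bad), "padj")
})

test_that("GWAS table reader converts 1-based catalog positions", {
  f <- withr::local_tempfile()
  writeLines(c("SNPS\tCHR_ID\tCHR_POS\tP-VALUE\tMAPPED_TRAIT",
               "rs1\tchr1\t101\t5e-9\todontogenesis"), f)
  got <- read_gwas_table(f)
  expect_equal(got$pos, 100)
  expect_equal(got$pvalue, 5e-9)
})
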