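make_track <- function(chrom, start, end, state, id = "s1") {
  segmentation_track(id, data.frame(chrom = chrom, start = start, end = end,
                                    label = as.character(state), strand = ".",
                                    stringsAsFactors = FALSE))
}

test_that("strong-enhancer extraction selects states 8-10 and merges adjacency", {
  tr <- make_track("chr1", c(0, 200, 400), c(200, 400, 600), c(1, 8, 9))
  got <- extract_strong_enhancers(tr)
  expect_equal(got$kind, "strong")
  expect_equal(got$intervals[, c("chrom", "start", "end")],
               data.frame(chrom = "chr1", start = 200, end = 600),
               ignore_attr = TRUE)

  weak <- make_track("chr1", c(0, 100), c(100, 200), c(1, 1))
  expect_equal(nrow(extract_strong_enhancers(weak)$intervals), 0)

  # prefixed ChromHMM labels parse by leading integer
  pre <- make_track("chr1", 0, 100, "9_EnhA1")
  expect_equal(nrow(extract_strong_enhancers(pre)$intervals), 1)

  expect_error(extract_strong_enhancers(tr, strong_states = 19), "\\[1, 18\\]")
  expect_error(make_track("chr1", 0, 100, 21), "outside")
})

test_that("extraction equals brute-force per-base state selection", {
  withr::local_seed(7)
  len <- 10000
  for (i in 1:25) {
    # random non-overlapping segmentation over a toy chromosome
    cuts <- sort(sample(1:(len - 1), 19))
    bounds <- c(0, cuts, len)
    states <- sample(1:18, length(bounds) - 1, replace = TRUE)
    tr <- make_track("chrT", bounds[-length(bounds)], bounds[-1], states)
    got <- extract_strong_enhancers(tr)$intervals
    segs <- data.frame(chrom = "chrT", start = bounds[-length(bounds)],
                       end = bounds[-1])[states %in% 8:10, ]
    expect_same_cover(got, oracle_mask_op(segs, chroms = "chrT", len = len))
  }
})

test_that("whole-element specificity drops any-overlap enhancers; trim subtracts", {
  strong <- function(iv, id) enhancer_set(id, "strong", iv)
  tg <- strong(genomic_intervals("chr1", 0, 100), "tooth")
  bg <- strong(genomic_intervals("chr1", 50, 60), "liver")
  expect_equal(nrow(tissue_specific_enhancers(tg, list(bg))$intervals), 0)
  got <- tissue_specific_enhancers(tg, list(bg), mode = "trim")$intervals
  expect_same_cover(got, data.frame(chrom = "chr1", start = c(0, 60), end = c(50, 100)))

  other <- strong(genomic_intervals("chr2", 0, 100), "liver")
  expect_equal(nrow(tissue_specific_enhancers(tg, list(other))$intervals), 1)

  expect_warning(res <- tissue_specific_enhancers(tg, list()), "background")
  expect_equal(res$kind, "tissue_specific")
  expect_same_cover(res$intervals, tg$intervals)
})

test_that("tissue-specific sets stay within strong and shrink monotonically", {
  withr::local_seed(13)
  for (i in 1:20) {
    tg <- enhancer_set("tooth", "strong", merge_intervals(random_intervals(30)))
    bgs <- lapply(1:5, function(j)
      enhancer_set(paste0("bg", j), "strong", merge_intervals(random_intervals(20))))
    for (mode in c("remove_whole", "trim")) {
      prev_bp <- Inf
      for (k in 1:5) {
        res <- tissue_specific_enhancers(tg, bgs[1:k], mode = mode)
        # every base of the result is a base of the strong set
        left <- subtract_intervals(res$intervals, tg$intervals)
        expect_equal(nrow(left), 0)
        bp <- sum(res$intervals$end - res$intervals$start)
        expect_lte(bp, prev_bp)
        prev_bp <- bp
      }
    }
    # trim mode equals the mask-oracle difference against pooled backgrounds
    pooled <- do.call(rbind, lapply(bgs, function(b) b$intervals[, 1:3]))
    got <- tissue_specific_enhancers(tg, bgs, mode = "trim")$intervals
    expect_same_cover(got, oracle_mask_op(tg$intervals, pooled,
                                          c("chrA", "chrB"), 10000, "subtract"))
  }
})

test_that("coordinate-map projection handles identity, empty and partial maps", {
  es <- enhancer_set("tooth", "strong",
                     genomic_intervals(rep("chr1", 3), c(0, 100, 4000),
                                       c(50, 150, 4100)))
  ident <- data.frame(src_chrom = "chr1", src_start = 0, src_end = 10000,
                      dst_chrom = "chr1", dst_start = 0, dst_end = 10000)
  got <- apply_coordinate_map(es, ident)
  expect_same_cover(got$intervals, es$intervals)
  expect_equal(attr(got, "mapping_report")$n_dropped, 0)

  none <- ident[0, ]
  got <- apply_coordinate_map(es, none)
  expect_equal(nrow(got$intervals), 0)
  expect_equal(attr(got, "mapping_report")$n_dropped, 3)

  # shift-by-1000 block covering only the first two enhancers
  shift <- data.frame(src_chrom = "chr1", src_start = 0, src_end = 200,
                      dst_chrom = "chr9", dst_start = 1000, dst_end = 1200)
  got <- apply_coordinate_map(es, shift)
  expect_same_cover(got$intervals,
                    data.frame(chrom = "chr9", start = c(1000, 1100),
                               end = c(1050, 1150)))
  expect_equal(attr(got, "mapping_report")$n_mapped, 2)

  bad <- data.frame(src_chrom = "chr1", src_start = 100, src_end = 50,
                    dst_chrom = "chr1", dst_start = 0, dst_end = 50)
  expect_error(apply_coordinate_map(es, bad), "inverted")
})
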