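# Independent oracles used across the suite. Each reimplements the checked
# operation by brute force from first principles (per-base boolean masks,
# exhaustive enumeration, all-pairs scans, spreadsheet-style arithmetic) and
# never calls the package functions it is checking.

## ---- per-base boolean-mask oracle (toy chromosomes <= 10 kb) -------------

# mask[i] == TRUE iff 0-based position i-1 is covered
mask_from_intervals <- function(ivs, chrom, len) {
  m <- rep(FALSE, len)
  sub <- ivs[ivs$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    lo <- max(0, sub$start[i]); hi <- min(len, sub$end[i])
    if (hi > lo) m[(lo + 1):hi] <- TRUE
  }
  m
}

mask_to_intervals <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(data.frame(chrom = character(), start = numeric(),
                                    end = numeric()))
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

oracle_mask_op <- function(a, b = NULL, chroms, len, op = c("merge", "subtract", "intersect")) {
  op <- match.arg(op)
  out <- lapply(chroms, function(ch) {
    ma <- mask_from_intervals(a, ch, len)
    m <- switch(op,
                merge = ma,
                subtract = ma & !mask_from_intervals(b, ch, len),
                intersect = ma & mask_from_intervals(b, ch, len))
    mask_to_intervals(m, ch)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), len = 10000,
                             max_w = 400) {
  start <- sample.int(len - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = pmin(start + w, len),
             label = NA_character_, strand = ".", stringsAsFactors = FALSE)
}

expect_same_cover <- function(got, oracle) {
  expect_equal(got[, c("chrom", "start", "end")], oracle[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
}

## ---- Fisher exact: exhaustive fixed-margin enumeration -------------------

# probability-ordering two-tailed p from lchoose-based pmf (no dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d; r <- a + b; c1 <- a + c
  lo <- max(0, c1 - (N - r)); hi <- min(r, c1)
  xs <- lo:hi
  lp <- lchoose(r, xs) + lchoose(N - r, c1 - xs) - lchoose(N, c1)
  p <- exp(lp)
  min(1, sum(p[p <= p[xs == a] * (1 + 1e-7)]))
}

## ---- hand step-up BH oracle ----------------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

## ---- all-pairs enhancer-to-gene assignment oracle ------------------------

oracle_assign_counts <- function(ivs, domains) {
  vapply(seq_len(nrow(domains)), function(j) {
    sum(ivs$chrom == domains$chrom[j] &
          pmin(ivs$end, domains$ext_end[j]) -
          pmax(ivs$start, domains$ext_start[j]) >= 1)
  }, numeric(1))
}

## ---- spreadsheet-style scoring oracle ------------------------------------

oracle_score_row <- function(is_marker, dental, gwas, n_tse, n_flags, vista,
                             te, deg) {
  bucket <- c(0, 1, 1, 2, 2, 3, 3, 4)[pmin(n_tse, 7) + 1]
  is_marker + dental + gwas + bucket + n_flags + vista + te + deg
}

## ---- misc ----------------------------------------------------------------

hyper_mean <- function(k, t, n) k * t / n
hyper_var <- function(k, t, n) k * (t / n) * (1 - t / n) * (n - k) / (n - 1)

gene_fixture <- function(ids, chrom, start, end, strand = "+") {
  gene_records(data.frame(gene_id = ids, symbol = toupper(ids), chrom = chrom,
                          start = start, end = end, strand = strand,
                          ortholog_id = NA_character_, stringsAsFactors = FALSE))
}
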