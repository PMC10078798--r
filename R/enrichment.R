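# Statistical layer: label-permutation set enrichment with an empirical p,
# Benjamini-Hochberg correction, and Fisher exact 2x2 contingency analysis.
# The permutation null draws gene sets uniformly at random from the universe,
# so the expected overlap is the hypergeometric mean |query||target|/|universe|.

# Run expr under a local, seeded RNG without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Permutation test for gene-set overlap enrichment
#'
#' Observes `|query %in% target|` and compares it with the overlaps of
#' `n_perm` uniform random subsets of the universe of size `|query|`. The
#' empirical p-value carries the +1 correction, `(1 + #extreme)/(1 + n_perm)`,
#' so it is never exactly zero and its resolution floor is `1/(n_perm + 1)`.
#' Enrichment and depletion tails are both computed; `p_empirical` is the tail
#' matching the observed direction (`observed >= null_mean` counts as
#' enrichment).
#'
#' @param query,target,universe character vectors of gene ids; `query` and
#'   `target` must be subsets of `universe`.
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed; identical inputs and seed give identical results.
#' @return An `EnrichmentResult`: list with `observed`, `null_mean`, `fold`
#'   (`observed/null_mean`), `log2_fold` (defined only when `null_mean > 0`),
#'   `p_empirical`, `direction`, `p_enrichment`, `p_depletion`, `n_perm`,
#'   `seed`.
#' @export
permutation_set_enrichment <- function(query, target, universe,
                                       n_perm = 10000, seed = 1) {
  query <- unique(query); target <- unique(target); universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (!all(query %in% universe)) stop("query must be a subset of universe")
  if (!all(target %in% universe)) stop("target must be a subset of universe")
  stopifnot(n_perm >= 1)
  k <- length(query)
  n_univ <- length(universe)
  in_target <- universe %in% target
  observed <- sum(query %in% target)
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(in_target[sample.int(n_univ, k)]), numeric(1))
  })
  null_mean <- mean(null)
  p_enr <- (1 + sum(null >= observed)) / (1 + n_perm)
  p_dep <- (1 + sum(null <= observed)) / (1 + n_perm)
  direction <- if (observed >= null_mean) "enrichment" else "depletion"
  fold <- if (null_mean > 0) observed / null_mean else if (observed > 0) Inf else NaN
  structure(list(observed = observed, null_mean = null_mean, fold = fold,
                 log2_fold = if (is.finite(fold) && fold > 0) log2(fold) else NA_real_,
                 p_empirical = if (direction == "enrichment") p_enr else p_dep,
                 direction = direction,
                 p_enrichment = p_enr, p_depletion = p_dep,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: observed %d vs null mean %.3f (fold %.2f, log2 %.2f)\n  %s p = %.4g  (n_perm = %d, seed = %d)\n",
    x$observed, x$null_mean, x$fold,
    ifelse(is.na(x$log2_fold), NaN, x$log2_fold),
    x$direction, x$p_empirical, x$n_perm, x$seed))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement; input order preserved.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Fisher exact test on a 2x2 table
#'
#' The table is
#' \preformatted{          outcome  no outcome
#'  group A        a           b
#'  group B        c           d }
#' The two-tailed p sums the hypergeometric point probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (probability-ordering definition, with the standard
#' `1 + 1e-7` relative tie tolerance). The fold reported as `prop_ratio` is
#' the ratio of group proportions `(a/(a+b)) / (c/(c+d))`; `odds_ratio` is the
#' sample odds ratio `ad/bc` (`Inf` when `bc = 0` and `ad > 0`).
#'
#' @param a,b,c,d non-negative integer cell counts; `a + b` and `c + d` must
#'   be positive (each group proportion must be defined).
#' @return A `ContingencyResult`: list with `table`, `odds_ratio`,
#'   `prop_ratio`, `p_two_tailed`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells) | cells < 0 | cells != floor(cells)))
    stop("cell counts must be non-negative integers")
  if (a + b == 0 || c + d == 0)
    stop("undefined proportion: a+b and c+d must be positive")
  m <- a + c; n_ <- b + d; k <- a + b
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  structure(list(table = matrix(cells, 2, 2, byrow = TRUE,
                                dimnames = list(c("groupA", "groupB"),
                                                c("outcome", "no_outcome"))),
                 odds_ratio = or,
                 prop_ratio = (a / (a + b)) / (c / (c + d)),
                 p_two_tailed = p),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio = %.3g, proportion ratio = %.3g, two-tailed p = %.3g\n",
              x$odds_ratio, x$prop_ratio, x$p_two_tailed))
  invisible(x)
}

#' Module-level enrichment flags
#'
#' For every co-expression module and each of three evidence categories
#' (tooth-enhancer target genes, dental-phenotype ontology genes, DEGs), runs
#' [permutation_set_enrichment()] of the module members against the category,
#' BH-adjusts the empirical p-values across the whole module-by-category
#' family, and flags a module enriched when `fold > 1` and adjusted
#' `p <= alpha`. An empty category yields a `FALSE` flag, not an error.
#'
#' @param module_members named list: module -> character vector of gene ids.
#' @param te_targets,dental_ontology_genes,deg_set category gene sets.
#' @param universe gene universe containing all module members.
#' @param n_perm permutations per test.
#' @param seed base seed; test `i` of the family uses `seed + i`.
#' @param alpha adjusted-p threshold for a flag (default 0.05).
#' @return `data.frame` with `module`, `enr_te_targets`,
#'   `enr_dental_ontology`, `enr_degs`; the full per-test table (module,
#'   category, observed, expected, fold, p, padj, seed) is in attribute
#'   `"detail"`.
#' @export
module_enrichment_flags <- function(module_members, te_targets,
                                    dental_ontology_genes, deg_set, universe,
                                    n_perm = 10000, seed = 1, alpha = 0.05) {
  stopifnot(is.list(module_members), length(names(module_members)) == length(module_members))
  cats <- list(enr_te_targets = unique(te_targets),
               enr_dental_ontology = unique(dental_ontology_genes),
               enr_degs = unique(deg_set))
  grid <- expand.grid(module = names(module_members), category = names(cats),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    members <- module_members[[grid$module[i]]]
    target <- intersect(cats[[grid$category[i]]], universe)
    if (length(target) == 0)
      return(list(observed = 0, null_mean = 0, fold = 0, p_empirical = 1,
                  p_enrichment = 1, seed = seed + i))
    r <- permutation_set_enrichment(members, target, universe,
                                    n_perm = n_perm, seed = seed + i)
    r$fold <- if (is.nan(r$fold)) 0 else r$fold
    r
  })
  detail <- data.frame(grid,
                       observed = vapply(res, `[[`, numeric(1), "observed"),
                       expected = vapply(res, `[[`, numeric(1), "null_mean"),
                       fold = vapply(res, `[[`, numeric(1), "fold"),
                       p = vapply(res, `[[`, numeric(1), "p_enrichment"),
                       seed = vapply(res, function(r) as.numeric(r$seed), numeric(1)),
                       stringsAsFactors = FALSE)
  detail$padj <- bh_adjust(detail$p)
  detail$flag <- detail$fold > 1 & detail$padj <= alpha
  out <- data.frame(module = names(module_members), stringsAsFactors = FALSE)
  for (cat_ in names(cats)) {
    sub <- detail[detail$category == cat_, ]
    out[[cat_]] <- sub$flag[match(out$module, sub$module)]
  }
  attr(out, "detail") <- detail
  out
}
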