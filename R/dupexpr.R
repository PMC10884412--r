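## Exact conditional test for expression divergence between duplicates.
## Conditioning on a pair's read total within a sample removes the need
## for library-size normalisation: under equal expression the count of one
## member is Binomial(total, p0).

#' Exact conditional test for one duplicate pair in one sample
#'
#' Two-sided exact binomial test of `count_a` successes in
#' `count_a + count_b` trials against the null proportion `null_p0`
#' (computed with [stats::binom.test], which sums the probabilities of all
#' outcomes at most as likely as the observed one).
#'
#' @param count_a,count_b non-negative integer read counts (their sum must
#'   be >= 1; all-zero pairs are excluded upstream)
#' @param null_p0 null proportion in (0, 1); 0.5 for equal expression, or
#'   `len_a/(len_a+len_b)` for a CDS-length-corrected null
#' @return the exact two-sided p value
#' @export
pair_exact_test <- function(count_a, count_b, null_p0 = 0.5) {
  if (null_p0 <= 0 || null_p0 >= 1) {
    stop("null_p0 must be inside (0, 1)", call. = FALSE)
  }
  if (count_a < 0 || count_b < 0 || count_a + count_b < 1) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  binom.test(count_a, count_a + count_b, p = null_p0)$p.value
}

#' Test all duplicate pairs for expression divergence
#'
#' Every two-copy pair is tested once per tissue and replicate; every
#' three-copy group contributes its three pairwise tests. Within each
#' tissue and replicate the Bonferroni divisor is the number of tests
#' actually performed there (pairs with both counts zero are excluded). A
#' pair is called a differentially expressed gene pair (DEGP) in a tissue
#' only when it is significant at `alpha` after correction in every
#' replicate, with the same direction of imbalance throughout.
#'
#' @param counts a `count_matrix` (see [simulate_expression_counts()] and
#'   [read_counts()])
#' @param pairs data.frame of pairs to test (`gene_a`, `gene_b`); defaults
#'   to the pairs carried by `counts`. Three-copy groups should be supplied
#'   pre-expanded to their three pairs (see [groups_to_pairs()]).
#' @param alpha significance level on the corrected p value (default 0.05)
#' @param null_p0 null proportion; a single value, or a vector along
#'   `pairs` for length-corrected nulls
#' @return data.frame of class `dup_pair_tests`: one row per pair x tissue
#'   x replicate with counts, raw and corrected p, significance and
#'   direction, plus per-pair-tissue `consistent_significant`
#' @export
test_duplicate_groups <- function(counts, pairs = counts$pairs,
                                  alpha = 0.05, null_p0 = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  samples <- counts$samples
  if (nrow(samples) == 0L) stop("no samples", call. = FALSE)
  tissues <- unique(samples$tissue)
  p0 <- rep_len(null_p0, nrow(pairs))
  rows <- list()
  for (ti in tissues) {
    reps <- samples$replicate[samples$tissue == ti]
    if (length(reps) == 0L) stop("tissue with zero replicates: ", ti,
                                 call. = FALSE)
    for (r in reps) {
      col <- samples$sample[samples$tissue == ti & samples$replicate == r]
      ca <- counts$counts[pairs$gene_a, col]
      cb <- counts$counts[pairs$gene_b, col]
      testable <- (ca + cb) >= 1L
      n_tests <- sum(testable)
      p <- rep(NA_real_, nrow(pairs))
      p[testable] <- vapply(which(testable), function(i) {
        pair_exact_test(ca[i], cb[i], p0[i])
      }, numeric(1))
      p_adj <- pmin(p * n_tests, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = pairs$gene_a, gene_b = pairs$gene_b, tissue = ti,
        replicate = r, count_a = ca, count_b = cb, null_p0 = p0,
        p_value = p, corrected_p = p_adj,
        significant = !is.na(p_adj) & p_adj < alpha,
        direction = sign(ca / pmax(ca + cb, 1L) - p0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  key <- paste(out$gene_a, out$gene_b, out$tissue, sep = "\r")
  consistent <- vapply(split(seq_len(nrow(out)), key), function(i) {
    all(out$significant[i]) && length(unique(out$direction[i])) == 1L
  }, logical(1))
  out$consistent_significant <- consistent[key]
  rownames(out) <- NULL
  class(out) <- c("dup_pair_tests", class(out))
  pk_log("test_duplicate_groups", n_pairs = nrow(pairs),
         n_tissues = length(tissues), alpha = alpha)
  out
}

#' Expand retention groups to testable duplicate pairs
#'
#' Two-copy groups yield their single pair; three-copy groups yield all
#' three pairwise combinations.
#'
#' @param groups `groups` data.frame from [classify_retention_groups()]
#' @return data.frame with `gene_a`, `gene_b`, `group_id`, `copy_class`
#' @export
groups_to_pairs <- function(groups) {
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    if (groups$copy_class[i] < 2L) next
    m <- sort(strsplit(groups$members[i], ";", fixed = TRUE)[[1]])
    cmb <- combn(m, 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = cmb[1, ], gene_b = cmb[2, ], group_id = groups$group_id[i],
      copy_class = groups$copy_class[i], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      group_id = character(0), copy_class = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise differentially expressed gene pairs
#'
#' Per-tissue counts and fractions of DEGPs among tested pairs, the set of
#' pairs divergent in every tissue, and (when `groups` is supplied) counts
#' of retention groups with at least one DEGP, by copy class.
#'
#' @param tests a `dup_pair_tests`
#' @param groups optional `groups` data.frame for class-level counts
#' @return list with `per_tissue` (data.frame: `tissue`, `n_tested_pairs`,
#'   `n_degp`, `fraction`), `all_tissue_pairs` (pair ids DEGP in every
#'   tissue), and optionally `groups_by_class`
#' @export
summarize_degp <- function(tests, groups = NULL) {
  pair_id <- paste(tests$gene_a, tests$gene_b, sep = "|")
  per_pt <- unique(data.frame(pair = pair_id, tissue = tests$tissue,
                              degp = tests$consistent_significant,
                              tested = !is.na(tests$p_value),
                              stringsAsFactors = FALSE))
  agg <- lapply(split(per_pt, per_pt$tissue), function(df) {
    tested <- tapply(df$tested, df$pair, all)
    degp <- tapply(df$degp, df$pair, all)
    data.frame(tissue = df$tissue[1], n_tested_pairs = sum(tested),
               n_degp = sum(degp & tested),
               fraction = if (sum(tested)) sum(degp & tested) / sum(tested)
               else NA_real_, stringsAsFactors = FALSE)
  })
  per_tissue <- do.call(rbind, agg)
  rownames(per_tissue) <- NULL
  degp_by_tissue <- lapply(split(per_pt, per_pt$tissue), function(df) {
    unique(df$pair[df$degp])
  })
  all_tissue <- Reduce(intersect, degp_by_tissue)
  out <- list(per_tissue = per_tissue, all_tissue_pairs = all_tissue)
  if (!is.null(groups)) {
    degp_any <- unique(unlist(degp_by_tissue))
    degp_genes <- unique(unlist(strsplit(degp_any, "|", fixed = TRUE)))
    out$groups_by_class <-
      intersect_groups_with_gene_list(groups, degp_genes)$counts_by_class
  }
  out
}
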