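## Homology filtering, collinear block chaining and karyotype arithmetic.

#' Filter all-vs-all homology hits
#'
#' Keeps hits with identity at or above `min_identity`, e-value strictly
#' below `max_evalue`, and both query and subject coverage at or above
#' `min_coverage`. Note the strict inequality on the e-value: a hit at
#' exactly the threshold is removed.
#'
#' @param hits data.frame of homology hits (see [read_homology()])
#' @param min_identity percent identity floor (default 30)
#' @param max_evalue e-value ceiling, exclusive (default 1e-10)
#' @param min_coverage aligned fraction floor for both sequences
#'   (default 0.30)
#' @return the retained hits
#' @export
filter_homology_hits <- function(hits, min_identity = 30,
                                 max_evalue = 1e-10, min_coverage = 0.30) {
  keep <- hits$identity >= min_identity &
    hits$evalue < max_evalue &
    hits$coverage_q >= min_coverage &
    hits$coverage_s >= min_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  pk_log("filter_homology_hits", n_in = nrow(hits), n_kept = nrow(out),
         min_identity = min_identity, max_evalue = max_evalue,
         min_coverage = min_coverage)
  out
}

## Chain scoring: sum of anchor scores minus gap_penalty per skipped rank
## unit in either genome. Both quantities are needed by the brute-force
## oracle, so they live in one place.
chain_gap_cost <- function(ra, rb, gap_penalty) {
  if (length(ra) < 2L) return(0)
  sum((abs(diff(ra)) - 1) + (abs(diff(rb)) - 1)) * gap_penalty
}

chain_score <- function(idx, anchors, gap_penalty) {
  sum(anchors$score[idx]) -
    chain_gap_cost(anchors$ra[idx], anchors$rb[idx], gap_penalty)
}

# Best chain with >= min_genes anchors among anchors of one chromosome
# pair and one orientation (rb ascending after sign flip). DP with a
# capped count dimension guarantees the count constraint exactly.
best_chain_dp <- function(anchors, min_genes, max_gap, gap_penalty) {
  n <- nrow(anchors)
  if (n < min_genes) return(NULL)
  ord <- order(anchors$ra, anchors$rb)
  a <- anchors[ord, , drop = FALSE]
  K <- min_genes
  score <- matrix(-Inf, n, K)   # score[i, c]: best ending at i with
  prev <- matrix(0L, n, K)      # min(count, K) = c
  score[, 1] <- a$score
  for (i in seq_len(n)) {
    if (i == 1L) next
    jj <- seq_len(i - 1L)
    dra <- a$ra[i] - a$ra[jj]
    drb <- a$rb[i] - a$rb[jj]
    ok <- dra > 0 & drb > 0 & dra <= max_gap & drb <= max_gap
    if (!any(ok)) next
    jj <- jj[ok]
    step <- a$score[i] - gap_penalty * ((dra[ok] - 1) + (drb[ok] - 1))
    for (cc in seq_len(K)) {
      tgt <- min(cc + 1L, K)    # cc = K keeps extending at the cap
      cand <- score[jj, cc] + step
      m <- which.max(cand)
      if (is.finite(cand[m]) && cand[m] > score[i, tgt] + 1e-12) {
        score[i, tgt] <- cand[m]
        prev[i, tgt] <- jj[m] + (cc - 1L) * n
      }
    }
  }
  if (!any(is.finite(score[, K]))) return(NULL)
  besti <- which.max(score[, K])
  chain <- integer(0)
  i <- besti; cc <- K
  repeat {
    chain <- c(i, chain)
    p <- prev[i, cc]
    if (p == 0L) break
    cc_prev <- p %/% n + ifelse(p %% n == 0L, 0L, 1L)
    i_prev <- p - (cc_prev - 1L) * n
    i <- i_prev; cc <- cc_prev
  }
  list(idx = ord[chain], score = score[besti, K])
}

#' Chain filtered homology hits into collinear syntenic blocks
#'
#' Weighted longest-collinear-chain dynamic programming over anchor pairs,
#' per chromosome pair and orientation, gap-penalised. Blocks are extracted
#' best-first: the highest-scoring chain with at least `min_genes` anchors
#' is recorded, its anchors are removed, and the search repeats, so each
#' anchor belongs to at most one block. Adjacent tandem duplicates hitting
#' one partner gene are collapsed to the best-scoring hit before chaining.
#'
#' @param hits filtered homology hits
#' @param genes_a,genes_b gene tables of the two genomes (query and
#'   subject sides of `hits`)
#' @param min_genes minimum anchors per block (default 5)
#' @param max_gap maximum rank gap between consecutive anchors, in rank
#'   units on either genome (default 25)
#' @param gap_penalty score deducted per skipped rank unit (default 0.5;
#'   anchor scores are bitscores scaled by `score_scale`)
#' @param score_scale divisor applied to bitscores before chaining so the
#'   gap penalty operates on a comparable scale (default 100)
#' @param collapse_tandem collapse adjacent-rank duplicates (default TRUE)
#' @return list of blocks; each block is a list with `species_a`,
#'   `species_b`, `chrom_a`, `chrom_b`, `orientation` ("same"/"inverted"),
#'   `score`, `n_anchors` and an `anchors` data.frame (`gene_a`, `gene_b`,
#'   `rank_a`, `rank_b`, `bitscore`)
#' @export
chain_collinear_blocks <- function(hits, genes_a, genes_b, min_genes = 5L,
                                   max_gap = 25L, gap_penalty = 0.5,
                                   score_scale = 100,
                                   collapse_tandem = TRUE) {
  same_species <- identical(genes_a$species[1], genes_b$species[1])
  ia <- match(hits$query, genes_a$gene_id)
  ib <- match(hits$subject, genes_b$gene_id)
  ok <- !is.na(ia) & !is.na(ib)
  anc <- data.frame(gene_a = hits$query[ok], gene_b = hits$subject[ok],
                    chrom_a = genes_a$chromosome[ia[ok]],
                    chrom_b = genes_b$chromosome[ib[ok]],
                    ra = genes_a$rank[ia[ok]], rb = genes_b$rank[ib[ok]],
                    bitscore = hits$bitscore[ok], stringsAsFactors = FALSE)
  anc <- anc[anc$gene_a != anc$gene_b, , drop = FALSE]
  if (same_species) {
    # one canonical orientation per unordered pair
    flip <- anc$chrom_a > anc$chrom_b |
      (anc$chrom_a == anc$chrom_b & anc$ra > anc$rb)
    anc[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "ra", "rb")] <-
      anc[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rb", "ra")]
    anc <- anc[!duplicated(anc[, c("gene_a", "gene_b")]), , drop = FALSE]
  }
  anc$score <- anc$bitscore / score_scale
  blocks <- list()
  for (key in unique(paste(anc$chrom_a, anc$chrom_b, sep = "\r"))) {
    ch <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- anc[anc$chrom_a == ch[1] & anc$chrom_b == ch[2], , drop = FALSE]
    if (collapse_tandem) sub <- collapse_tandem_anchors(sub)
    repeat {
      best <- NULL; best_orient <- NULL
      for (orient in c("same", "inverted")) {
        s2 <- sub
        if (orient == "inverted") s2$rb <- -s2$rb
        res <- best_chain_dp(s2, min_genes, max_gap, gap_penalty)
        if (!is.null(res) &&
            (is.null(best) || res$score > best$score + 1e-12 ||
             (abs(res$score - best$score) <= 1e-12 &&
              sum(sub$bitscore[res$idx]) > sum(sub$bitscore[best$idx])))) {
          best <- res; best_orient <- orient
        }
      }
      if (is.null(best)) break
      bl <- sub[best$idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(
        species_a = genes_a$species[1], species_b = genes_b$species[1],
        chrom_a = ch[1], chrom_b = ch[2], orientation = best_orient,
        score = best$score, n_anchors = nrow(bl),
        anchors = data.frame(gene_a = bl$gene_a, gene_b = bl$gene_b,
                             rank_a = bl$ra, rank_b = bl$rb,
                             bitscore = bl$bitscore,
                             stringsAsFactors = FALSE))
      sub <- sub[-best$idx, , drop = FALSE]
      if (nrow(sub) < min_genes) break
    }
  }
  pk_log("chain_collinear_blocks", n_anchors_in = nrow(anc),
         n_blocks = length(blocks), min_genes = min_genes,
         max_gap = max_gap, gap_penalty = gap_penalty)
  blocks
}

# Collapse runs of anchors that hit the same partner gene from adjacent
# ranks (tandem arrays) to the best-scoring member of the run.
collapse_tandem_anchors <- function(sub) {
  for (side in c("a", "b")) {
    gene_col <- paste0("gene_", setdiff(c("a", "b"), side))
    rank_col <- if (side == "a") "ra" else "rb"
    sub <- sub[order(sub[[gene_col]], sub[[rank_col]]), , drop = FALSE]
    if (nrow(sub) < 2L) next
    new_run <- c(TRUE, sub[[gene_col]][-1] != sub[[gene_col]][-nrow(sub)] |
                   diff(sub[[rank_col]]) > 1L)
    run_id <- cumsum(new_run)
    keep <- unlist(lapply(split(seq_len(nrow(sub)), run_id), function(i) {
      i[which.max(sub$bitscore[i])]
    }), use.names = FALSE)
    sub <- sub[sort(keep), , drop = FALSE]
  }
  sub
}

#' Synteny depth of a reference genome under a query species
#'
#' For every reference gene, the number of distinct query blocks whose
#' reference-side anchor range covers its rank. A genome descended from an
#' unreduced triplication shows a modal depth of 3 against the
#' pre-triplication outgroup (the "3:1" synteny ratio).
#'
#' @param blocks blocks from [chain_collinear_blocks()] with the reference
#'   genome on side `a`
#' @param ref_genes reference gene table
#' @return list with `depth` (named integer vector per reference gene),
#'   `histogram` (table of depths) and `modal_depth`
#' @export
synteny_depth_ratio <- function(blocks, ref_genes) {
  depth <- setNames(integer(nrow(ref_genes)), ref_genes$gene_id)
  for (bl in blocks) {
    sel <- ref_genes$chromosome == bl$chrom_a &
      ref_genes$rank >= min(bl$anchors$rank_a) &
      ref_genes$rank <= max(bl$anchors$rank_a)
    depth[sel] <- depth[sel] + 1L
  }
  hist <- table(depth)
  modal <- as.integer(names(hist)[which.max(hist)])
  list(depth = depth, histogram = hist, modal_depth = modal)
}

#' Expected haploid chromosome number after a ladder of polyploidies
#'
#' The purely multiplicative expectation if no fusion or fission occurred:
#' the base number times every multiplication factor, e.g.
#' `7 * 3 * 2 * 2 * 2 = 168` for three successive doublings on a
#' triplicated seven-chromosome ancestor, or `8 * 3 = 24` after one
#' triplication of an eight-chromosome ancestor.
#'
#' @param n_base ancestral haploid chromosome number (integer >= 1)
#' @param multipliers integer multiplication factors (each >= 1; may be
#'   empty)
#' @return integer chromosome number
#' @export
expected_ploidy_ladder <- function(n_base, multipliers = integer(0)) {
  stopifnot_count(n_base, "n_base", 1L)
  if (length(multipliers)) {
    for (m in multipliers) stopifnot_count(m, "multipliers", 1L)
  }
  as.integer(n_base * prod(as.integer(multipliers)))
}

#' Count fusion, fission and inversion events from a karyotype painting
#'
#' Adjacency-based lower bounds on the rearrangement history: a descendant
#' chromosome carrying segments of `k` distinct ancestral chromosomes
#' implies `k - 1` fusions; an ancestral chromosome split across `m`
#' descendant chromosomes implies `m - 1` fissions; a sign change between
#' adjacent segments of the same ancestral chromosome is an inversion
#' breakpoint. This is a segment-adjacency surrogate, not a
#' rearrangement-distance solver.
#'
#' @param map karyotype map: named list, one element per descendant
#'   chromosome, each a data.frame with columns `anc_chrom` and `sign`
#'   (+1/-1), segments in chromosome order
#' @param ancestral_chroms character vector of valid ancestral chromosome
#'   names (segments mapping elsewhere are an error)
#' @return list with `fusion`, `fission`, `inversion_breakpoints`
#' @export
count_rearrangement_events <- function(map, ancestral_chroms) {
  all_anc <- unlist(lapply(map, function(m) m$anc_chrom), use.names = FALSE)
  bad <- setdiff(all_anc, ancestral_chroms)
  if (length(bad)) {
    stop("segments map to unknown ancestral chromosome(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  fusion <- sum(vapply(map, function(m) {
    length(unique(m$anc_chrom)) - 1L
  }, integer(1)))
  anc_spread <- table(unlist(lapply(map, function(m) unique(m$anc_chrom))))
  fission <- sum(pmax(as.integer(anc_spread) - 1L, 0L))
  inv <- sum(vapply(map, function(m) {
    if (nrow(m) < 2L) return(0L)
    same <- m$anc_chrom[-1] == m$anc_chrom[-nrow(m)]
    flip <- m$sign[-1] != m$sign[-nrow(m)]
    sum(same & flip)
  }, integer(1)))
  list(fusion = fusion, fission = fission, inversion_breakpoints = inv)
}

#' Karyotype map of a simulated descendant against its ancestor
#'
#' Run-length encodes each descendant chromosome into maximal segments of
#' genes from one ancestral chromosome with one orientation. For a
#' post-polyploidy descendant the reference karyotype is the post-WGT one,
#' so each subgenome copy of an ancestral chromosome counts as its own
#' ancestral chromosome (`<anc_chrom>_<subgenome>`).
#'
#' @param layout a descendant gene table carrying `anc_chrom`,
#'   `subgenome` and `sign`
#' @return a karyotype map as consumed by [count_rearrangement_events()]
#' @export
karyotype_map_from_layout <- function(layout) {
  layout$.anc <- if (!is.null(layout$subgenome)) {
    paste0(layout$anc_chrom, "_", layout$subgenome)
  } else layout$anc_chrom
  out <- lapply(split(layout, layout$chromosome), function(df) {
    df <- df[order(df$rank), , drop = FALSE]
    brk <- c(TRUE, df$.anc[-1] != df$.anc[-nrow(df)] |
               df$sign[-1] != df$sign[-nrow(df)])
    seg <- cumsum(brk)
    data.frame(anc_chrom = df$.anc[brk], sign = df$sign[brk],
               n_genes = as.integer(table(seg)), stringsAsFactors = FALSE)
  })
  out[unique(layout$chromosome)]
}
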