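# Independent oracles, kept free of the implementation paths they check.

# Exhaustive best collinear chain (>= min_genes anchors) by depth-first
# enumeration of every valid chain; same scoring as the chaining DP.
brute_best_chain <- function(anc, min_genes, max_gap, gap_penalty) {
  n <- nrow(anc)
  best <- NULL
  extend <- function(chain) {
    last <- chain[length(chain)]
    for (j in seq_len(n)) {
      dra <- anc$ra[j] - anc$ra[last]
      drb <- anc$rb[j] - anc$rb[last]
      if (dra > 0 && drb > 0 && dra <= max_gap && drb <= max_gap) {
        extend(c(chain, j))
      }
    }
    if (length(chain) >= min_genes) {
      sc <- sum(anc$score[chain]) -
        gap_penalty * sum((diff(anc$ra[chain]) - 1) +
                            (diff(anc$rb[chain]) - 1))
      if (is.null(best) || sc > best$score + 1e-12) {
        best <<- list(idx = chain, score = sc)
      }
    }
  }
  for (i in seq_len(n)) extend(i)
  best
}

# best-first block extraction mirrored on the brute-force search
brute_block_set <- function(anc, min_genes, max_gap, gap_penalty) {
  blocks <- list()
  sub <- anc
  repeat {
    same <- brute_best_chain(sub, min_genes, max_gap, gap_penalty)
    inv_anc <- sub; inv_anc$rb <- -inv_anc$rb
    inv <- brute_best_chain(inv_anc, min_genes, max_gap, gap_penalty)
    pick <- NULL
    if (!is.null(same) && (is.null(inv) || same$score >= inv$score)) {
      pick <- same
    } else if (!is.null(inv)) pick <- inv
    if (is.null(pick)) break
    blocks[[length(blocks) + 1L]] <- list(ra = sub$ra[pick$idx],
                                          score = pick$score)
    sub <- sub[-pick$idx, , drop = FALSE]
    if (nrow(sub) < min_genes) break
  }
  blocks
}

# exact two-sided binomial p value by full enumeration
enumerate_binom_p <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1L] * (1 + 1e-12)])
}
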