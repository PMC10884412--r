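## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
##
## Counting estimator: synonymous/nonsynonymous site fractions per codon,
## observed differences resolved by equal-weight averaging over all minimal
## mutational pathways (pathways through stop codons are excluded; if every
## pathway hits a stop, the exclusion is waived). Changes that create a stop
## codon are counted as nonsynonymous in the site tally.

BASES <- c("A", "C", "G", "T")

codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  syn_sites <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { syn_sites[i] <- NA_real_; next }
    cd <- strsplit(codons[i], "")[[1]]
    f <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, cd[pos])) {
        mut <- cd; mut[pos] <- b
        maa <- gc_tab[paste(mut, collapse = "")]
        if (maa == aa[i]) f <- f + 1 / 3  # stop mutants count as nonsyn
      }
    }
    syn_sites[i] <- f
  }
  # Pairwise (sd, nd) over minimal pathways, precomputed for all codon pairs.
  sd_mat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  step_class <- function(c1, c2) {
    a1 <- gc_tab[c1]; a2 <- gc_tab[c2]
    if (a2 == "*" || a1 == "*") return("stop")
    if (a1 == a2) "syn" else "nonsyn"
  }
  for (i in seq_len(64)) {
    for (j in seq_len(64)) {
      if (aa[i] == "*" || aa[j] == "*") next
      c1 <- strsplit(codons[i], "")[[1]]
      c2 <- strsplit(codons[j], "")[[1]]
      diff_pos <- which(c1 != c2)
      k <- length(diff_pos)
      if (k == 0L) { sd_mat[i, j] <- 0; nd_mat[i, j] <- 0; next }
      perms <- if (k == 1L) list(diff_pos) else {
        pm <- list()
        idx <- seq_len(k)
        permute <- function(v) {
          if (length(v) <= 1L) return(list(v))
          out <- list()
          for (q in seq_along(v)) {
            for (rest in permute(v[-q])) out[[length(out) + 1L]] <- c(v[q], rest)
          }
          out
        }
        lapply(permute(idx), function(o) diff_pos[o])
      }
      tally <- function(skip_stops) {
        sds <- numeric(0); nds <- numeric(0)
        for (path in perms) {
          cur <- c1; s <- 0; n <- 0; ok <- TRUE
          for (pos in path) {
            nxt <- cur; nxt[pos] <- c2[pos]
            cls <- step_class(paste(cur, collapse = ""), paste(nxt, collapse = ""))
            if (cls == "stop") {
              if (skip_stops) { ok <- FALSE; break }
              cls <- "nonsyn"
            }
            if (cls == "syn") s <- s + 1 else n <- n + 1
            cur <- nxt
          }
          if (ok) { sds <- c(sds, s); nds <- c(nds, n) }
        }
        if (length(sds)) c(mean(sds), mean(nds)) else NULL
      }
      res <- tally(TRUE)
      if (is.null(res)) res <- tally(FALSE)
      sd_mat[i, j] <- res[1]; nd_mat[i, j] <- res[2]
    }
  }
  codon_env$tab <- list(codons = codons, aa = aa, syn_sites = syn_sites,
                        sd = sd_mat, nd = nd_mat)
  codon_env$tab
}

split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori Ka/Ks for one aligned in-frame CDS pair
#'
#' Counts synonymous (S) and nonsynonymous (N) sites averaged over the two
#' sequences, resolves observed codon differences by equal-weight averaging
#' over minimal mutational pathways, and applies the Jukes-Cantor multiple-hit
#' correction `K = -3/4 log(1 - 4/3 p)` to both proportions. Codons
#' containing gaps or ambiguous bases in either sequence are dropped
#' pairwise before counting.
#'
#' @param cds_a,cds_b equal-length, in-frame aligned coding sequences
#'   (character strings, no internal stop codons)
#' @return a one-row data.frame of class `pair_ks` with columns `Ka`, `Ks`,
#'   `omega`, `S`, `N`, `Sd`, `Nd`, `n_codons`, `saturated`. `Ks`/`Ka` are
#'   `NA` with `saturated = TRUE` when the corrected proportion reaches the
#'   Jukes-Cantor ceiling (p >= 3/4). `omega` is `NA` when `Ks` is 0 or
#'   undefined.
#' @examples
#' ng86_ka_ks("TTTGGGAAA", "TTCGGGAAA")
#' @export
ng86_ka_ks <- function(cds_a, cds_b) {
  if (!is.character(cds_a) || !is.character(cds_b) ||
      length(cds_a) != 1L || length(cds_b) != 1L) {
    stop("cds_a and cds_b must be single character strings", call. = FALSE)
  }
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  tab <- codon_tables()
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[keep]; cb <- cb[keep]
  ia <- match(ca, tab$codons); ib <- match(cb, tab$codons)
  if (any(tab$aa[ia] == "*") || any(tab$aa[ib] == "*")) {
    stop("internal stop codon in aligned CDS", call. = FALSE)
  }
  n_codons <- length(ca)
  if (n_codons == 0L) stop("no ungapped codons to compare", call. = FALSE)
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * n_codons - S
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  saturated <- (pS >= 0.75) || (pN >= 0.75)
  jc <- function(p) -0.75 * log(1 - 4 / 3 * p)
  Ks <- if (saturated) NA_real_ else jc(pS)
  Ka <- if (saturated) NA_real_ else jc(pN)
  omega <- if (!saturated && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  out <- data.frame(Ka = Ka, Ks = Ks, omega = omega, S = S, N = N,
                    Sd = Sd, Nd = Nd, n_codons = n_codons,
                    saturated = saturated)
  class(out) <- c("pair_ks", class(out))
  out
}

#' Ka/Ks for a collection of aligned CDS pairs
#'
#' @param pairs a data.frame with columns `gene_a`, `gene_b` and aligned
#'   sequences in columns `cds_a`, `cds_b` (as produced by
#'   [simulate_codon_pairs()]), or a list of two-element character vectors.
#' @return data.frame with one row per pair: `gene_a`, `gene_b`, `Ka`, `Ks`,
#'   `omega`, `n_codons`, `saturated`
#' @export
ka_ks_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      ng86_ka_ks(pairs$cds_a[i], pairs$cds_b[i])
    })
    ids <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                      stringsAsFactors = FALSE)
  } else {
    res <- lapply(pairs, function(p) ng86_ka_ks(p[[1]], p[[2]]))
    ids <- data.frame(gene_a = paste0("a", seq_along(pairs)),
                      gene_b = paste0("b", seq_along(pairs)),
                      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  cbind(ids, out[, c("Ka", "Ks", "omega", "n_codons", "saturated")])
}
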