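## Readers and writers for every on-disk format. All readers validate and
## reject malformed input rather than repairing it; every writer/reader
## pair round-trips exactly. Coordinates are 1-based inclusive on disk
## (GFF convention); ranks are recomputed from coordinates on read.

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop("failed to parse ", path, ": ", conditionMessage(e),
                        call. = FALSE)
                 })
  miss <- setdiff(required_cols, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a gene position table
#'
#' Accepts the package's TSV gene table (`gene_id`, `species`,
#' `chromosome`, `start`, `end`, `strand`) or a GFF3 file (`.gff`/`.gff3`,
#' gene features; parsed with rtracklayer). Coordinates are 1-based
#' inclusive; ranks are recomputed from start positions within each
#' chromosome.
#'
#' @param path input file
#' @param species species label used when the file does not carry one
#' @return gene table data.frame with `rank` recomputed
#' @export
read_gene_table <- function(path, species = NULL) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    df <- data.frame(gene_id = as.character(gr$ID),
                     species = if (is.null(species)) "unknown" else species,
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_checked(path, c("gene_id", "species", "chromosome",
                                   "start", "end", "strand"))
  }
  validate_gene_table(df, path)
}

validate_gene_table <- function(df, path = "<in-memory>") {
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start <= 0 | df$end <= 0)
  if (length(bad)) {
    stop(sprintf("%s line %d: non-positive coordinate", path, bad[1] + 1L),
         call. = FALSE)
  }
  bad <- which(df$start > df$end)
  if (length(bad)) {
    stop(sprintf("%s line %d: start > end", path, bad[1] + 1L),
         call. = FALSE)
  }
  dup <- duplicated(paste(df$species, df$gene_id))
  if (any(dup)) {
    stop(sprintf("%s line %d: duplicate gene_id '%s'",
                 path, which(dup)[1] + 1L, df$gene_id[which(dup)[1]]),
         call. = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop(sprintf("%s line %d: strand must be + or -", path,
                 which(!df$strand %in% c("+", "-"))[1] + 1L),
         call. = FALSE)
  }
  df <- df[order(match(df$chromosome, unique(df$chromosome)), df$start), ,
           drop = FALSE]
  df$rank <- unlist(lapply(split(df$start, df$chromosome)[unique(df$chromosome)],
                           seq_along), use.names = FALSE)
  df$sign <- ifelse(df$strand == "+", 1L, -1L)
  rownames(df) <- NULL
  df
}

#' Write a gene table as TSV
#' @param genes gene table
#' @param path output file
#' @export
write_gene_table <- function(genes, path) {
  cols <- c("gene_id", "species", "chromosome", "start", "end", "strand")
  write.table(genes[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

HOMOLOGY_COLS <- c("query", "subject", "identity", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                   "bitscore", "qlen", "slen")

#' Read a homology table (BLAST tabular plus sequence lengths)
#'
#' Expects the 12 standard tabular columns followed by query and subject
#' sequence lengths (BLAST's `-outfmt "6 std qlen slen"`), no header.
#' Coverages are computed per hit as alignment length over sequence
#' length.
#'
#' @param path tabular file
#' @return data.frame with `query`, `subject`, `identity`, `evalue`,
#'   `coverage_q`, `coverage_s`, `bitscore`
#' @export
read_homology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(HOMOLOGY_COLS)) {
    stop(sprintf("%s: expected %d tab-separated columns, found %d",
                 path, length(HOMOLOGY_COLS), ncol(df)), call. = FALSE)
  }
  names(df) <- HOMOLOGY_COLS
  num <- c("identity", "evalue", "bitscore", "length", "qlen", "slen")
  for (cc in num) {
    if (any(is.na(suppressWarnings(as.numeric(df[[cc]]))))) {
      stop(sprintf("%s line %d: non-numeric '%s'", path,
                   which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1],
                   cc), call. = FALSE)
    }
    df[[cc]] <- as.numeric(df[[cc]])
  }
  if (any(df$evalue < 0)) stop("negative e-value in ", path, call. = FALSE)
  data.frame(query = df$query, subject = df$subject,
             identity = df$identity, evalue = df$evalue,
             coverage_q = df$length / df$qlen,
             coverage_s = df$length / df$slen,
             bitscore = df$bitscore, stringsAsFactors = FALSE)
}

#' Write homology hits in BLAST tabular style
#'
#' Alignment length is encoded so that the coverage columns round-trip:
#' `qlen = length/coverage_q`, `slen = length/coverage_s`, with `length`
#' fixed at 1000.
#'
#' @param hits data.frame as returned by [read_homology()]
#' @param path output file
#' @export
write_homology <- function(hits, path) {
  len <- 1000
  out <- data.frame(hits$query, hits$subject, hits$identity, len, 0L, 0L,
                    1L, len, 1L, len, hits$evalue, hits$bitscore,
                    round(len / hits$coverage_q, 6),
                    round(len / hits$coverage_s, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a counts matrix with sample metadata in the header
#'
#' First column `gene_id`; remaining columns named `<tissue>.rep<k>`.
#'
#' @param path TSV file
#' @return a `count_matrix` (see [simulate_expression_counts()])
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path, "gene_id")
  cn <- setdiff(names(df), "gene_id")
  m <- regmatches(cn, regexec("^(.+)\\.rep(\\d+)$", cn))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) {
    stop(sprintf("%s: sample column '%s' is not <tissue>.rep<k>",
                 path, cn[bad[1]]), call. = FALSE)
  }
  samples <- data.frame(tissue = vapply(m, `[`, character(1), 2L),
                        replicate = as.integer(vapply(m, `[`, character(1),
                                                      3L)),
                        sample = cn, stringsAsFactors = FALSE)
  per_tissue <- split(samples$replicate, samples$tissue)
  for (ti in names(per_tissue)) {
    if (!setequal(per_tissue[[ti]], seq_len(max(per_tissue[[ti]])))) {
      stop(sprintf("%s: incomplete replicate labels for tissue '%s'",
                   path, ti), call. = FALSE)
    }
  }
  counts <- as.matrix(df[, cn, drop = FALSE])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop(path, ": counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  out <- list(counts = counts, samples = samples, pairs = NULL,
              truth_degp = NULL)
  class(out) <- "count_matrix"
  out
}

#' Write a counts matrix
#' @param cm a `count_matrix`
#' @param path output file
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree] and [ape::write.tree] so every
#' format used by the pipeline has an entry point here.
#'
#' @param path Newick file
#' @return for `read_newick`, an [ape::phylo] or list of them
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("failed to parse Newick in ", path, call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree a tree or list of trees
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write a folded site frequency spectrum table
#'
#' Columns: `freq_class` (1..floor(n/2)), `zero_fold`, `four_fold`.
#'
#' @param path TSV file
#' @param n_chrom number of sampled chromosomes the SFS was computed from
#' @return list with `sfs0`, `sfs4` (numeric vectors) and `n_chrom`
#' @export
read_sfs <- function(path, n_chrom) {
  df <- read_tsv_checked(path, c("freq_class", "zero_fold", "four_fold"))
  if (!identical(df$freq_class, seq_len(n_chrom %/% 2L))) {
    stop(path, ": freq_class must be 1..floor(n_chrom/2)", call. = FALSE)
  }
  if (any(df$zero_fold < 0) || any(df$four_fold < 0)) {
    stop(path, ": negative SFS counts", call. = FALSE)
  }
  list(sfs0 = df$zero_fold, sfs4 = df$four_fold, n_chrom = n_chrom)
}

#' @rdname read_sfs
#' @param sfs0,sfs4 folded spectra (equal length)
#' @export
write_sfs <- function(sfs0, sfs4, path) {
  stopifnot(length(sfs0) == length(sfs4))
  write.table(data.frame(freq_class = seq_along(sfs0), zero_fold = sfs0,
                         four_fold = sfs4),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write aligned CDS pairs as FASTA
#'
#' Pairs are stored as consecutive records named `<pair>|a` and
#' `<pair>|b`.
#'
#' @param path FASTA file
#' @return data.frame with `gene_a`, `gene_b`, `cds_a`, `cds_b`
#' @export
read_cds_pairs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  if (length(seqs) %% 2L != 0L) {
    stop(path, ": odd number of FASTA records", call. = FALSE)
  }
  ia <- seq(1L, length(seqs), 2L)
  data.frame(gene_a = sub("\\|a$", "", nm[ia]),
             gene_b = sub("\\|b$", "", nm[ia + 1L]),
             cds_a = as.character(seqs[ia]),
             cds_b = as.character(seqs[ia + 1L]),
             stringsAsFactors = FALSE)
}

#' @rdname read_cds_pairs
#' @param pairs data.frame with `gene_a`, `gene_b`, `cds_a`, `cds_b`
#' @export
write_cds_pairs <- function(pairs, path) {
  seqs <- character(2L * nrow(pairs))
  nm <- character(2L * nrow(pairs))
  seqs[c(TRUE, FALSE)] <- pairs$cds_a
  seqs[c(FALSE, TRUE)] <- pairs$cds_b
  nm[c(TRUE, FALSE)] <- paste0(pairs$gene_a, "|a")
  nm[c(FALSE, TRUE)] <- paste0(pairs$gene_b, "|b")
  x <- Biostrings::DNAStringSet(setNames(seqs, nm))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write candidate LTR retrotransposon tables
#'
#' @param path TSV with columns `element_id`, `ltr5_len`, `ltr3_len`,
#'   `spacing_to_next`, `ltr_similarity`, `has_gag_pol`,
#'   `ltr_divergence_K`, `family`
#' @return validated data.frame
#' @export
read_ltr_table <- function(path) {
  df <- read_tsv_checked(path, c("element_id", "ltr5_len", "ltr3_len",
                                 "spacing_to_next", "ltr_similarity",
                                 "has_gag_pol", "ltr_divergence_K",
                                 "family"))
  if (any(df$ltr5_len <= 0) || any(df$ltr3_len <= 0)) {
    stop(path, ": LTR lengths must be positive", call. = FALSE)
  }
  if (any(df$ltr_similarity < 0 | df$ltr_similarity > 100)) {
    stop(path, ": similarity must be in [0, 100]", call. = FALSE)
  }
  if (any(df$ltr_divergence_K < 0)) {
    stop(path, ": divergence K must be >= 0", call. = FALSE)
  }
  df$has_gag_pol <- as.logical(df$has_gag_pol)
  df
}

#' @rdname read_ltr_table
#' @param ltr data.frame of candidates
#' @export
write_ltr_table <- function(ltr, path) {
  write.table(ltr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-pair Ka/Ks results
#' @param pairs_ks data.frame from [ka_ks_pairs()]
#' @param path output TSV
#' @export
write_pairs_ks <- function(pairs_ks, path) {
  write.table(pairs_ks[, c("gene_a", "gene_b", "Ka", "Ks", "omega",
                           "n_codons", "saturated")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-pair Ka/Ks results
#' @rdname write_pairs_ks
#' @export
read_pairs_ks <- function(path) {
  read_tsv_checked(path, c("gene_a", "gene_b", "Ka", "Ks", "omega",
                           "n_codons", "saturated"))
}
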