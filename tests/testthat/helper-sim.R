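set_log_level("quiet")

# small, fast configuration used across unit tests
quick_config <- function(seed = 1L, n_anc_genes = 300L, ...) {
  sim_config(seed = seed, n_anc_genes = n_anc_genes, ...)
}

# gene table builder for hand-made synteny instances
toy_genes <- function(n, species = "A", chrom = "c1", prefix = species) {
  data.frame(gene_id = paste0(prefix, seq_len(n)), species = species,
             chromosome = chrom, start = (seq_len(n) - 1L) * 2000L + 1L,
             end = (seq_len(n) - 1L) * 2000L + 1000L, strand = "+",
             rank = seq_len(n), stringsAsFactors = FALSE)
}

toy_hits <- function(qa, sb, bitscore = 300, identity = 90,
                     evalue = 1e-50) {
  data.frame(query = qa, subject = sb, identity = identity,
             evalue = evalue, coverage_q = 1, coverage_s = 1,
             bitscore = bitscore, stringsAsFactors = FALSE)
}
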