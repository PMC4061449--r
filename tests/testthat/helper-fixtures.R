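# Shared fixtures, built in code.

# Hit table with one row per (read, species) hit.
make_hits <- function(read_id, species, read_length = 150L,
                      evalue = 1e-20, bitscore = 200) {
  data.frame(read_id = read_id, read_length = read_length,
             species = species, evalue = evalue, bitscore = bitscore,
             subject = paste0(gsub("[^A-Za-z0-9]+", "_", species), "_acc1"),
             stringsAsFactors = FALSE)
}

# binned_coverage with prescribed normalized values (for balance arithmetic
# tests where normalized vectors need not average to 1).
fake_bins <- function(normalized, bin_size = 500, contig = "chr1") {
  n <- length(normalized)
  structure(
    data.frame(bin_start = (seq_len(n) - 1L) * bin_size,
               bin_end = seq_len(n) * bin_size,
               bin_mean_depth = normalized,
               normalized = normalized),
    class = c("binned_coverage", "data.frame"),
    bin_size = as.integer(bin_size), contig = contig,
    genome_mean_depth = mean(normalized),
    genome_length = n * bin_size)
}

# Independent Gini oracle: mean absolute difference over all ordered pairs.
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}
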