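# Shared fixtures and independent oracles used across the suite.

# Random signed circular order over n synthetic gene labels.
random_signed_order <- function(n, p_minus = 0.5) {
  gene_order(
    sample(sprintf("g%02d", seq_len(n))),
    sample(c("+", "-"), n, replace = TRUE, prob = c(1 - p_minus, p_minus)),
    anchor = "g01"
  )
}

# Independent adjacency oracle: pairwise gene-end matching written as an
# explicit per-position loop, deliberately not sharing code with the
# package's vectorised implementation.
oracle_adjacency_set <- function(o) {
  lab <- o$label
  sgn <- ifelse(o$strand == "+", 1L, -1L)
  n <- length(lab)
  out <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    right <- if (sgn[i] > 0) paste0(lab[i], ".h") else paste0(lab[i], ".t")
    left <- if (sgn[j] > 0) paste0(lab[j], ".t") else paste0(lab[j], ".h")
    out[i] <- paste(sort(c(right, left)), collapse = "|")
  }
  out
}

oracle_shared_adjacencies <- function(a, b) {
  length(intersect(oracle_adjacency_set(a), oracle_adjacency_set(b)))
}

# Independent hand-derived intermediate of the shipped scenario: survivors
# of the two monomers after polarity-determined loss of the duplicated
# ancestral order, and the joined single-strand order before the trnT and
# trnC/trnQ events.
monomer1_survivors <- c(
  "trnI", "trnM", "nad2", "trnW", "cox1", "cox2", "trnK", "trnD", "atp8",
  "atp6", "cox3", "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE",
  "trnT", "nad6", "cob", "trnS2", "CR"
)

monomer2_survivors <- c(
  "trnQ", "trnC", "trnY", "trnF", "nad5", "trnH", "nad4", "nad4L", "trnP",
  "nad1", "trnL2", "trnL1", "rrnL", "trnV", "rrnS"
)

# monomer 1 survivors followed by monomer 2's survivors reversed (their
# polarity flipped to + by the 3'-3' join)
post_join_order <- c(monomer1_survivors, rev(monomer2_survivors))

# A tiny annotation table built in code.
toy_annotation <- function() {
  annotation_table(
    tibble::tibble(
      name = c("cox1", "trnK", "nad2"),
      category = c("PCG", "tRNA", "PCG"),
      start = c(1L, 301L, 365L),
      end = c(300L, 364L, 664L),
      strand = "+",
      start_codon = c("ATG", NA, "ATG"),
      stop_codon = c("TAA", NA, "TAG"),
      anticodon = c(NA, "AAG", NA)
    ),
    genome_length = 700
  )
}
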