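# Nucleotide composition, strand-asymmetry skews, and relative synonymous
# codon usage (RSCU) under the invertebrate mitochondrial genetic code.

#' Base composition and strand-asymmetry skews of a sequence
#'
#' Counts A/T/G/C (N and other IUPAC ambiguity codes are tallied separately
#' and excluded from all denominators) and computes
#' `AT-skew = (A - T) / (A + T)` and `GC-skew = (G - C) / (G + C)`, the
#' standard signed measures of strand compositional asymmetry.  A skew whose
#' denominator is zero is reported as `NA`.
#'
#' @param seq A single character string or `DNAString`.
#' @return A one-row tibble: `length`, counts `a`, `t`, `g`, `c`,
#'   `n_ambiguous`, percentages `a_pct` ... `c_pct`, `at_content`,
#'   `gc_content` (percent), `at_skew`, `gc_skew`.
#' @examples
#' composition_stats("AATTTGC")
#' @export
composition_stats <- function(seq) {
  seq <- as_genome_string(seq)
  if (nchar(seq) == 0) stop_mito("empty sequence")
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  a <- freq[["A"]]; t <- freq[["T"]]; g <- freq[["G"]]; c <- freq[["C"]]
  n_unamb <- a + t + g + c
  if (n_unamb == 0) stop_mito("sequence contains no unambiguous bases")
  pct <- function(x) 100 * x / n_unamb
  sk <- skew_from_percentages(pct(a), pct(t), pct(g), pct(c))
  tibble(
    length = nchar(seq),
    a = a, t = t, g = g, c = c,
    n_ambiguous = nchar(seq) - n_unamb,
    a_pct = pct(a), t_pct = pct(t), g_pct = pct(g), c_pct = pct(c),
    at_content = pct(a + t), gc_content = pct(g + c),
    at_skew = sk$at_skew, gc_skew = sk$gc_skew
  )
}

#' Skews from printed base percentages
#'
#' Direct application of `(A - T)/(A + T)` and `(G - C)/(G + C)` to
#' percentages as printed in a composition table; no re-normalisation is
#' applied, so the result is exactly what the printed figures imply.
#'
#' @param a_pct,t_pct,g_pct,c_pct Non-negative percentages (or any
#'   proportional measure; only ratios matter).
#' @return A one-row tibble with `at_skew` and `gc_skew`; a skew is `NA`
#'   when both members of its pair are zero.
#' @examples
#' skew_from_percentages(25.3, 40.9, 24.2, 9.7)
#' @export
skew_from_percentages <- function(a_pct, t_pct, g_pct, c_pct) {
  vals <- c(a_pct, t_pct, g_pct, c_pct)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_mito("percentages must be finite and non-negative")
  }
  at <- if (a_pct + t_pct == 0) NA_real_ else (a_pct - t_pct) / (a_pct + t_pct)
  gc <- if (g_pct + c_pct == 0) NA_real_ else (g_pct - c_pct) / (g_pct + c_pct)
  tibble(at_skew = at, gc_skew = gc)
}

#' Per-partition composition of an annotated genome
#'
#' Composition and skews for the whole mitogenome and for each feature
#' category (PCGs, tRNAs, rRNAs, control region), each partition taken as
#' the concatenation of its features' sequences (minus-strand features
#' reverse-complemented); overlapping bases count once per feature.
#'
#' @param t A `mito_annotation`.
#' @param seq Genome sequence (string or `DNAString`).
#' @return A tibble with a `partition` column followed by the
#'   [composition_stats()] columns.
#' @export
partition_composition <- function(t, seq) {
  assert_annotation(t)
  seq <- as_genome_string(seq)
  parts <- c(list(mitogenome = seq),
             lapply(stats::setNames(nm = mito_categories()), function(cat) {
               paste(feature_sequences(t, seq, categories = cat), collapse = "")
             }))
  parts <- parts[vapply(parts, nchar, 1L) > 0]
  bind_rows(imap(parts, function(s, nm) {
    mutate(composition_stats(s), partition = nm, .before = 1)
  }))
}

# ---- RSCU --------------------------------------------------------------------

#' Invertebrate mitochondrial genetic code
#'
#' NCBI translation table 5 as a named character vector (codon to amino-acid
#' one-letter symbol, `*` for stop), via [Biostrings::getGeneticCode()].
#'
#' @export
mito_genetic_code <- function() {
  Biostrings::getGeneticCode("5")
}

# Synonymous families for mitochondrial codon-usage tables: codons sharing
# an amino acid AND a codon box (first two nucleotides), so that Leu splits
# into UUR/CUN and Ser into UCN/AGN -- mirroring the separate tRNA
# isoacceptors (trnL1/trnL2, trnS1/trnS2).
rscu_families <- function() {
  code <- mito_genetic_code()
  tibble(
    codon = names(code),
    amino_acid = unname(code),
    family = paste0(unname(code), "_", substr(names(code), 1, 2))
  )
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * family_size / total_family_count`: the observed
#' count of a codon divided by its expectation were all members of its
#' synonymous family used uniformly.  Families follow the invertebrate
#' mitochondrial code with Leu and Ser split by codon box (UUR vs CUN, UCN
#' vs AGN), the convention of mitogenome codon-usage tables.  Within every
#' family that is used at all, mean RSCU is exactly 1; codons of an unused
#' family carry RSCU 0 by convention.
#'
#' @param cds_list Character vector (or list) of coding sequences, each read
#'   5' to 3'.
#' @param trim Drop incomplete terminal codons (truncated stops) before
#'   counting (default)?  With `trim = FALSE` a length not divisible by 3 is
#'   an error.
#' @return An `rscu_table` tibble: `codon`, `amino_acid`, `family`,
#'   `family_size`, `count`, `rscu`.
#' @examples
#' rscu(c("TTATTG"))
#' @export
rscu <- function(cds_list, trim = TRUE) {
  cds_list <- vapply(as.list(cds_list), as_genome_string, character(1))
  if (length(cds_list) == 0) stop_mito("no coding sequences given")
  codons <- unlist(lapply(cds_list, function(s) {
    len <- nchar(s)
    if (trim) {
      len <- (len %/% 3L) * 3L
    } else if (len %% 3L != 0L) {
      stop_mito("sequence length not a multiple of 3 (and trim = FALSE)")
    }
    if (len == 0L) return(character(0))
    substring(s, seq(1L, len, by = 3L), seq(3L, len, by = 3L))
  }))
  fam <- rscu_families()
  bad <- setdiff(unique(codons), fam$codon)
  if (length(bad) > 0) {
    stop_mito(sprintf("non-ACGT codons in input: %s",
                      paste(bad, collapse = ", ")))
  }
  counts <- table(factor(codons, levels = fam$codon))
  fam |>
    mutate(count = as.integer(counts[.data$codon])) |>
    group_by(.data$family) |>
    mutate(
      family_size = n(),
      family_total = sum(.data$count),
      rscu = ifelse(.data$family_total == 0, 0,
                    .data$count * .data$family_size / .data$family_total)
    ) |>
    ungroup() |>
    select("codon", "amino_acid", "family", "family_size", "count", "rscu") |>
    structure(class = c("rscu_table", class(tibble())))
}

# ---- FASTA -------------------------------------------------------------------

#' Read and write single-record genome FASTA files
#'
#' Thin wrappers over Biostrings with uppercase normalisation; the genomes
#' handled here are single circular molecules, so exactly one record is
#' expected on read.
#'
#' @param path File path.
#' @return `read_fasta()`: a single uppercase character string, named by the
#'   record header; `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1) {
    stop_mito(sprintf("expected exactly 1 FASTA record, found %d", length(ss)))
  }
  stats::setNames(str_to_upper(as.character(ss[[1]])), names(ss)[1])
}

#' @rdname read_fasta
#' @param seq A single character string.
#' @param name FASTA header for the record.
#' @export
write_fasta <- function(seq, path, name = "sequence") {
  ss <- Biostrings::DNAStringSet(as_genome_string(seq))
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
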