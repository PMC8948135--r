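# Feature-annotation tables: parsing, validation, and the derived statistics
# a mitogenome description paper prints (intergenic spacers, gene overlaps,
# partition lengths, start/stop codon inventories).
#
# Coordinates are 1-based fully closed intervals on a circular genome, the
# convention of GenBank feature tables; no origin-wrapping features are
# accepted.

annotation_cols <- c("name", "category", "start", "end", "strand",
                     "start_codon", "stop_codon", "anticodon")

#' Build a validated annotation table
#'
#' @param features A data frame with columns `name`, `category` (one of
#'   `PCG`, `tRNA`, `rRNA`, `control_region`), `start`, `end` (1-based
#'   inclusive), `strand` (`+`/`-`), and optional `start_codon`,
#'   `stop_codon`, `anticodon` (`NA` when absent).
#' @param genome_length Total genome size in bp.
#' @return A `mito_annotation` tibble sorted by `start`, with a `length`
#'   column and the genome length attached as an attribute.
#' @export
annotation_table <- function(features, genome_length) {
  features <- as_tibble(features)
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
  }
  missing <- setdiff(annotation_cols, names(features))
  if (length(missing) > 0) {
    stop_mito(sprintf("annotation is missing columns: %s",
                      paste(missing, collapse = ", ")))
  }
  features <- features[annotation_cols]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features <- arrange(features, .data$start)
  features$length <- features$end - features$start + 1L
  out <- new_tibble(as.list(features), nrow = nrow(features),
                    class = "mito_annotation")
  attr(out, "genome_length") <- as.integer(genome_length)
  validate_annotation(out)
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("# Mitogenome annotation: %d features on a %s bp circular genome\n",
              nrow(x), format(genome_length(x), big.mark = ",")))
  NextMethod()
}

#' Genome length of an annotation table
#' @param t A `mito_annotation`.
#' @export
genome_length <- function(t) {
  assert_annotation(t)
  attr(t, "genome_length")
}

assert_annotation <- function(t, arg = "t") {
  if (!inherits(t, "mito_annotation")) {
    stop_mito(sprintf("`%s` must be an annotation table (see read_annotation())",
                      arg))
  }
  invisible(t)
}

validate_annotation <- function(t) {
  gl <- attr(t, "genome_length")
  if (!is.integer(gl) || length(gl) != 1 || is.na(gl) || gl < 1) {
    stop_mito("genome_length must be a positive integer")
  }
  fail <- function(name, what) {
    stop_mito(sprintf("invalid feature '%s': %s", name, what),
              class = "mitorearrange_validation_error")
  }
  if (anyDuplicated(t$name)) {
    stop_mito(sprintf("duplicated feature names: %s",
                      paste(unique(t$name[duplicated(t$name)]), collapse = ", ")),
              class = "mitorearrange_validation_error")
  }
  for (i in seq_len(nrow(t))) {
    f <- t[i, ]
    if (is.na(f$start) || is.na(f$end)) fail(f$name, "non-integral coordinates")
    if (f$start < 1 || f$start > f$end || f$end > gl) {
      fail(f$name, sprintf("coordinates %d-%d violate 1 <= start <= end <= %d",
                           f$start, f$end, gl))
    }
    if (!f$strand %in% c("+", "-")) fail(f$name, "strand must be '+' or '-'")
    if (!f$category %in% mito_categories()) {
      fail(f$name, sprintf("unknown category '%s'", f$category))
    }
    expected <- category_for_name(f$name)
    if (!is.na(expected) && expected != f$category) {
      fail(f$name, sprintf("category '%s' inconsistent with name (expected '%s')",
                           f$category, expected))
    }
    is_pcg <- f$category == "PCG"
    if (is_pcg && (is.na(f$start_codon) || is.na(f$stop_codon))) {
      fail(f$name, "protein-coding genes need start and stop codons")
    }
    if (!is_pcg && (!is.na(f$start_codon) || !is.na(f$stop_codon))) {
      fail(f$name, "start/stop codons are only meaningful for PCGs")
    }
  }
  t
}

#' Read and write feature-annotation tables
#'
#' Tab-separated with a header row and columns `name`, `category`, `start`,
#' `end`, `strand`, `start_codon`, `stop_codon`, `anticodon` (`.` for
#' absent).  A comment line `# genome_length=<bp>` carries the genome size;
#' alternatively pass `genome_length` explicitly.  The table is validated and
#' sorted by start coordinate.
#'
#' @param path File path.
#' @param genome_length Genome size in bp; overrides any header comment.
#' @return `read_annotation()`: a `mito_annotation`; `write_annotation()`:
#'   `path`, invisibly.
#' @examples
#' t <- read_annotation(mitorearrange_example("polydesmus_gzcs2019_features.tsv"))
#' nrow(t)
#' @export
read_annotation <- function(path, genome_length = NULL) {
  if (!file.exists(path)) stop_mito(sprintf("no such annotation file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)) == 0 || all(trimws(lines) == "")) {
    stop_mito(sprintf("annotation file is empty: %s", path),
              class = "mitorearrange_parse_error")
  }
  comments <- lines[startsWith(trimws(lines), "#")]
  gl_line <- grep("genome_length\\s*=", comments, value = TRUE)
  if (is.null(genome_length)) {
    if (length(gl_line) == 0) {
      stop_mito("genome_length not given and no '# genome_length=' header found",
                class = "mitorearrange_parse_error")
    }
    genome_length <- as.integer(sub(".*genome_length\\s*=\\s*(\\d+).*", "\\1",
                                    gl_line[1]))
  }
  body_idx <- which(!startsWith(trimws(lines), "#") & trimws(lines) != "")
  if (length(body_idx) < 2) {
    stop_mito(sprintf("annotation file has no data rows: %s", path),
              class = "mitorearrange_parse_error")
  }
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, annotation_cols)) {
    stop_mito(sprintf("unexpected header (line %d); expected: %s",
                      body_idx[1], paste(annotation_cols, collapse = ", ")),
              class = "mitorearrange_parse_error")
  }
  rows <- lapply(body_idx[-1], function(ln) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(annotation_cols)) {
      stop_mito(sprintf("malformed row at line %d: %d fields (expected %d)",
                        ln, length(fields), length(annotation_cols)),
                class = "mitorearrange_parse_error")
    }
    fields[fields == "."] <- NA_character_
    if (is.na(suppressWarnings(as.integer(fields[3]))) ||
        is.na(suppressWarnings(as.integer(fields[4])))) {
      stop_mito(sprintf("non-integral coordinates at line %d", ln),
                class = "mitorearrange_parse_error")
    }
    stats::setNames(as.list(fields), annotation_cols)
  })
  df <- bind_rows(lapply(rows, as_tibble))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  annotation_table(df, genome_length)
}

#' @rdname read_annotation
#' @param t A `mito_annotation`.
#' @export
write_annotation <- function(t, path) {
  assert_annotation(t)
  out <- t[annotation_cols]
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    out[[col]][is.na(out[[col]])] <- "."
  }
  lines <- c(
    sprintf("# genome_length=%d", genome_length(t)),
    paste(annotation_cols, collapse = "\t"),
    do.call(paste, c(unname(as.list(out)), sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' The shipped Polydesmus sp. GZCS-2019 annotation table
#'
#' The 38-feature annotation (13 PCGs, 22 tRNAs, 2 rRNAs, control region) of
#' the 15,036 bp *Polydesmus* sp. GZCS-2019 mitogenome (GenBank MZ677220).
#'
#' @return A `mito_annotation`.
#' @export
polydesmus_annotation <- function() {
  read_annotation(mitorearrange_example("polydesmus_gzcs2019_features.tsv"))
}

# ---- spacers and overlaps ----------------------------------------------------

#' Intergenic spacers and gene overlaps
#'
#' For every consecutive pair of features (in start order) the signed gap is
#' `downstream_start - upstream_end - 1`: positive gaps are intergenic
#' spacers, negative gaps overlaps, zero abutting genes.  The circular
#' closing pair (last feature back to the first across the origin) is
#' included as a record flagged `circular`; the scalar summaries cover the
#' linear pairs only, matching the convention of printed annotation tables,
#' whose intergenic column has no closing entry.
#'
#' @param t A `mito_annotation`.
#' @return A `spacer_report`: list with the `records` tibble (`upstream`,
#'   `downstream`, `gap`, `circular`) and summary fields `n_spacers`,
#'   `total_spacer_bp`, `min_spacer`, `max_spacer`, `n_overlaps`,
#'   `total_overlap_bp`, `max_overlap_bp`, `circular_gap`.  [tidy()] returns
#'   the records, [glance()] the summary row.
#' @examples
#' rep <- spacer_overlap_report(polydesmus_annotation())
#' glance(rep)
#' @export
spacer_overlap_report <- function(t) {
  assert_annotation(t)
  gl <- genome_length(t)
  t <- t[order(t$start), ]
  n <- nrow(t)
  if (n >= 2) {
    lin <- tibble(
      upstream = t$name[-n],
      downstream = t$name[-1],
      gap = t$start[-1] - t$end[-n] - 1L,
      circular = FALSE
    )
  } else {
    lin <- tibble(upstream = character(0), downstream = character(0),
                  gap = integer(0), circular = logical(0))
  }
  closing <- tibble(
    upstream = t$name[n], downstream = t$name[1],
    gap = gl - t$end[n] + t$start[1] - 1L,
    circular = TRUE
  )
  records <- bind_rows(lin, closing)
  sp <- lin$gap[lin$gap > 0]
  ov <- lin$gap[lin$gap < 0]
  structure(
    list(
      records = records,
      n_spacers = length(sp),
      total_spacer_bp = sum(sp),
      min_spacer = if (length(sp)) min(sp) else NA_integer_,
      max_spacer = if (length(sp)) max(sp) else NA_integer_,
      n_overlaps = length(ov),
      total_overlap_bp = sum(abs(ov)),
      max_overlap_bp = if (length(ov)) max(abs(ov)) else NA_integer_,
      circular_gap = closing$gap
    ),
    class = "spacer_report"
  )
}

#' @export
print.spacer_report <- function(x, ...) {
  cat(sprintf(
    "# Spacers: %d regions, %d bp (range %s-%s); overlaps: %d locations, %d bp (max %s); origin gap %d bp\n",
    x$n_spacers, x$total_spacer_bp, x$min_spacer, x$max_spacer,
    x$n_overlaps, x$total_overlap_bp, x$max_overlap_bp, x$circular_gap
  ))
  print(x$records, n = 10)
  invisible(x)
}

#' Total length per feature category
#'
#' Sums feature lengths (end - start + 1) per category; overlapping bases are
#' counted once per feature, the convention of printed partition tables.
#'
#' @param t A `mito_annotation`.
#' @return A tibble with `category`, `n_features`, `total_bp`, and the
#'   partition's share of the genome in percent.
#' @export
partition_lengths <- function(t) {
  assert_annotation(t)
  out <- t |>
    as_tibble() |>
    mutate(category = factor(.data$category, levels = mito_categories())) |>
    group_by(.data$category) |>
    summarise(n_features = n(), total_bp = sum(.data$length), .groups = "drop") |>
    arrange(.data$category)
  out$category <- as.character(out$category)
  out$pct_of_genome <- round(100 * out$total_bp / genome_length(t), 1)
  out
}

# ---- codons ------------------------------------------------------------------

#' Start and stop codon inventory of the protein-coding genes
#'
#' Reads the first triplet and the trailing (possibly truncated) stop of each
#' PCG from the genome sequence.  Features on the minus strand are
#' reverse-complemented before reading.  The trailing stop is the last
#' `length %% 3` bases (a complete triplet when the length is a multiple of
#' three) and is classified into `TAA`, `TAG`, `TA`, `T`, or `other`;
#' truncated stops are completed to TAA by post-transcriptional
#' polyadenylation, a biological note that is deliberately not applied
#' computationally.
#'
#' @param t A `mito_annotation`.
#' @param seq Genome sequence: a single character string or `DNAString`.
#' @return A tibble with one row per PCG: `gene`, `start_codon`,
#'   `stop_codon`, `stop_class`.
#' @export
codon_inventory <- function(t, seq) {
  assert_annotation(t)
  seq <- as_genome_string(seq)
  if (nchar(seq) != genome_length(t)) {
    stop_mito(sprintf("sequence length %d does not match genome_length %d",
                      nchar(seq), genome_length(t)))
  }
  pcgs <- filter(as_tibble(t), .data$category == "PCG")
  rows <- pmap(list(pcgs$name, pcgs$start, pcgs$end, pcgs$strand),
               function(name, start, end, strand) {
    len <- end - start + 1L
    if (len < 6) stop_mito(sprintf("PCG '%s' shorter than 6 nt", name))
    s <- substr(seq, start, end)
    if (strand == "-") s <- revcomp(s)
    rem <- len %% 3L
    stop_len <- if (rem == 0L) 3L else rem
    stop_codon <- substr(s, len - stop_len + 1L, len)
    tibble(
      gene = name,
      start_codon = substr(s, 1L, 3L),
      stop_codon = stop_codon,
      stop_class = if (stop_codon %in% c("TAA", "TAG", "TA", "T")) stop_codon
                   else "other"
    )
  })
  bind_rows(rows)
}

as_genome_string <- function(seq) {
  if (inherits(seq, "DNAString") || inherits(seq, "DNAStringSet")) {
    seq <- as.character(seq)[1]
  }
  if (!is_scalar_chr(seq)) stop_mito("sequence must be a single string")
  str_to_upper(seq)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract feature sequences from a genome
#'
#' Minus-strand features are reverse-complemented so every sequence reads
#' 5' to 3' in its own transcription direction.
#'
#' @param t A `mito_annotation`.
#' @param seq Genome sequence (string or `DNAString`).
#' @param categories Restrict to these categories (default: all).
#' @return A named character vector of feature sequences.
#' @export
feature_sequences <- function(t, seq, categories = mito_categories()) {
  assert_annotation(t)
  seq <- as_genome_string(seq)
  tt <- filter(as_tibble(t), .data$category %in% categories)
  if (nrow(tt) == 0) return(stats::setNames(character(0), character(0)))
  out <- pmap(list(tt$start, tt$end, tt$strand), function(start, end, strand) {
    s <- substr(seq, start, end)
    if (strand == "-") revcomp(s) else s
  })
  stats::setNames(unlist(out), tt$name)
}
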