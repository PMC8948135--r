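# Synthetic-data generators: annotated genome sequences with controlled
# feature structure and base composition, and gene orders evolved under
# parameterised rearrangement events.  Everything downstream is testable
# against these without any real sequence.
#
# Base composition is realised by exact count allocation (largest-remainder
# rounding of the target percentages) followed by a seeded shuffle, so the
# realised composition of any partition deviates from its target only by
# rounding, well inside the documented +/-1% tolerance for partitions of
# 1 kb and more; start/stop codons are overwritten afterwards, which is the
# remaining (tiny) source of deviation.

#' Specify a synthetic annotated genome
#'
#' The specification states the gene inventory (lengths, strands, codons),
#' the signed spacer/overlap plan between consecutive features, and target
#' base percentages -- globally and, optionally, per feature category.
#'
#' @param features A data frame with columns `name`, `category`, `length`,
#'   `strand`, and optional `start_codon`, `stop_codon` (PCGs only),
#'   `anticodon`, and `gap_before` (signed gap in bp between the previous
#'   feature's end and this feature's start; defaults to 0; the first
#'   feature's `gap_before` offsets it from position 1).
#' @param composition Named percentages `c(A=,T=,G=,C=)` summing to 100 for
#'   the genome background, or a list with element `global` plus optional
#'   per-category elements (`PCG`, `tRNA`, `rRNA`, `control_region`).
#' @param closing_gap Unannotated bp between the last feature and the
#'   origin (completes the circle).
#' @param seed Mandatory integer seed; generation is deterministic per seed.
#' @return A `genome_spec`.
#' @export
genome_spec <- function(features, composition, closing_gap = 0, seed) {
  features <- as_tibble(features)
  req <- c("name", "category", "length", "strand")
  missing <- setdiff(req, names(features))
  if (length(missing) > 0) {
    stop_mito(sprintf("feature spec is missing columns: %s",
                      paste(missing, collapse = ", ")))
  }
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
  }
  if (!"gap_before" %in% names(features)) features$gap_before <- 0L
  features$gap_before[is.na(features$gap_before)] <- 0L
  if (any(features$length < 1)) stop_mito("feature lengths must be positive")
  if (!is.list(composition)) composition <- list(global = composition)
  if (is.null(composition$global)) {
    stop_mito("composition needs a `global` element (or be a single ATGC vector)")
  }
  for (nm in names(composition)) {
    comp <- composition[[nm]]
    # printed composition tables round to 1 dp, so their rows can sum to
    # 100 +/- a few tenths; accept that and renormalise at allocation time
    if (!setequal(names(comp), c("A", "T", "G", "C")) ||
        abs(sum(comp) - 100) > 0.5) {
      stop_mito(sprintf("composition '%s' must be named A/T/G/C percentages summing to 100", nm))
    }
  }
  if (missing(seed)) stop_mito("genome_spec() requires an explicit seed")
  structure(
    list(features = features, composition = composition,
         closing_gap = as.integer(closing_gap), seed = as.integer(seed)),
    class = "genome_spec"
  )
}

# Exact base counts for a target composition: largest-remainder allocation.
allocate_bases <- function(len, comp) {
  comp <- comp[c("A", "T", "G", "C")]
  raw <- len * comp / sum(comp)
  counts <- floor(raw)
  short <- len - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(comp))
}

random_bases <- function(len, comp) {
  counts <- allocate_bases(len, comp)
  sample(rep(c("A", "T", "G", "C"), times = counts))
}

#' Generate an annotated genome sequence from a specification
#'
#' Realises the spec's spacer/overlap plan exactly as feature coordinates,
#' fills the genome with bases matching the target composition (per
#' category when given, global elsewhere), and finally writes each PCG's
#' start codon and (possibly truncated) stop codon in place.  Deterministic
#' per seed.
#'
#' @param spec A [genome_spec()].
#' @return A list with `sequence` (single uppercase string) and `annotation`
#'   (a `mito_annotation`).
#' @examples
#' spec <- genome_spec(
#'   tibble::tibble(name = c("cox1", "trnK"), category = c("PCG", "tRNA"),
#'                  length = c(300, 64), strand = "+",
#'                  start_codon = c("ATG", NA), stop_codon = c("TAA", NA)),
#'   composition = c(A = 25, T = 41, G = 24, C = 10), seed = 1
#' )
#' g <- synth_genome(spec)
#' nchar(g$sequence)
#' @export
synth_genome <- function(spec) {
  if (!inherits(spec, "genome_spec")) stop_mito("`spec` must be a genome_spec")
  f <- spec$features
  start <- integer(nrow(f))
  end <- integer(nrow(f))
  pos <- 0L
  for (i in seq_len(nrow(f))) {
    start[i] <- pos + f$gap_before[i] + 1L
    if (start[i] < 1L) {
      stop_mito(sprintf("infeasible plan: feature '%s' would start at %d",
                        f$name[i], start[i]))
    }
    if (i > 1 && start[i] <= start[i - 1]) {
      stop_mito(sprintf("infeasible plan: feature '%s' would not sort after '%s'",
                        f$name[i], f$name[i - 1]))
    }
    end[i] <- start[i] + f$length[i] - 1L
    pos <- max(pos, end[i])
  }
  gl <- pos + spec$closing_gap
  ann <- annotation_table(
    tibble(name = f$name, category = f$category, start = start, end = end,
           strand = f$strand, start_codon = f$start_codon,
           stop_codon = f$stop_codon, anticodon = f$anticodon),
    genome_length = gl
  )
  seq_chr <- with_seed(spec$seed, {
    bases <- random_bases(gl, spec$composition$global)
    # per-category composition overwrites feature spans (later features win
    # inside overlaps)
    for (i in seq_len(nrow(f))) {
      comp <- spec$composition[[f$category[i]]]
      if (!is.null(comp)) {
        bases[start[i]:end[i]] <- random_bases(f$length[i], comp)
      }
    }
    bases
  })
  # start/stop codons written last so they survive composition fills
  for (i in which(f$category == "PCG")) {
    sc <- f$start_codon[i]
    if (!is.na(sc)) {
      codon <- strsplit(sc, "")[[1]]
      if (f$strand[i] == "+") {
        seq_chr[start[i]:(start[i] + 2L)] <- codon
      } else {
        seq_chr[end[i]:(end[i] - 2L)] <- chartr("ACGT", "TGCA", codon)
      }
    }
    st <- f$stop_codon[i]
    if (!is.na(st)) {
      codon <- strsplit(st, "")[[1]]
      k <- length(codon)
      if (f$strand[i] == "+") {
        seq_chr[(end[i] - k + 1L):end[i]] <- codon
      } else {
        seq_chr[(start[i] + k - 1L):start[i]] <- chartr("ACGT", "TGCA", codon)
      }
    }
  }
  list(sequence = paste(seq_chr, collapse = ""), annotation = ann)
}

#' Genome specification mirroring the Polydesmus sp. GZCS-2019 mitogenome
#'
#' Lengths, strands, codons and the signed spacer/overlap plan are taken
#' from the shipped annotation table, and the per-partition target base
#' percentages from its published composition table (mitogenome A 25.3 /
#' T 40.9 / G 24.2 / C 9.7; PCG, tRNA, rRNA, and control-region partitions
#' likewise).  Generating from this spec reproduces the annotation's
#' spacer/overlap statistics by construction; the sequence itself is
#' synthetic.
#'
#' @param seed Mandatory integer seed.
#' @return A `genome_spec`.
#' @export
polydesmus_genome_spec <- function(seed) {
  ann <- polydesmus_annotation()
  gaps <- c(0L, ann$start[-1] - ann$end[-nrow(ann)] - 1L)
  features <- tibble(
    name = ann$name, category = ann$category, length = ann$length,
    strand = ann$strand, start_codon = ann$start_codon,
    stop_codon = ann$stop_codon, anticodon = ann$anticodon,
    gap_before = gaps
  )
  genome_spec(
    features,
    composition = list(
      global = c(A = 25.3, T = 40.9, G = 24.2, C = 9.7),
      PCG = c(A = 22.5, T = 42.3, G = 25.1, C = 9.9),
      tRNA = c(A = 31.2, T = 36.6, G = 22.0, C = 10.1),
      rRNA = c(A = 33.1, T = 37.1, G = 20.8, C = 9.0),
      control_region = c(A = 34.6, T = 38.4, G = 21.9, C = 5.0)
    ),
    closing_gap = genome_length(ann) - max(ann$end),
    seed = seed
  )
}

# ---- evolved gene orders -----------------------------------------------------

#' Specify a simulated gene-order evolution
#'
#' Events are drawn one at a time: `inversion` (random contiguous segment,
#' reversed with orientations flipped), `tdrl` (random segment duplicated in
#' tandem with a random loss pattern), or `tdnl_rc` (the composite
#' whole-genome duplication + polarity loss + 3'-3' join, which contributes
#' three steps to the history and leaves the order single-stranded).  Drawn
#' segment bounds and loss patterns are recorded explicitly in the emitted
#' history, so replaying it needs no RNG.
#'
#' @param start_order Circular `gene_order` to evolve.
#' @param n_events Number of events to draw.
#' @param kind_probs Named probabilities for `inversion`, `tdrl`, `tdnl_rc`;
#'   must sum to 1.
#' @param max_span Largest segment (genes) for inversion/TDRL draws.
#' @param seed Mandatory integer seed.
#' @return An `evolution_spec`.
#' @export
evolution_spec <- function(start_order, n_events,
                           kind_probs = c(inversion = 0.45, tdrl = 0.45,
                                          tdnl_rc = 0.1),
                           max_span = 6, seed) {
  assert_gene_order(start_order, "start_order")
  if (!setequal(names(kind_probs), c("inversion", "tdrl", "tdnl_rc")) ||
      abs(sum(kind_probs) - 1) > 1e-8 || any(kind_probs < 0)) {
    stop_mito("kind_probs must be probabilities over inversion/tdrl/tdnl_rc summing to 1")
  }
  if (missing(seed)) stop_mito("evolution_spec() requires an explicit seed")
  structure(
    list(start_order = start_order, n_events = as.integer(n_events),
         kind_probs = kind_probs[c("inversion", "tdrl", "tdnl_rc")],
         max_span = as.integer(max_span), seed = as.integer(seed)),
    class = "evolution_spec"
  )
}

#' Evolve a gene order under random rearrangement events
#'
#' @param spec An [evolution_spec()].
#' @return A list with `order` (the final circular `gene_order`), `history`
#'   (the list of applied [rearrangement_event()]s with all drawn parameters
#'   made explicit), and `start_order`.  Replaying the history from
#'   `start_order` reproduces `order` exactly.
#' @export
evolve_order <- function(spec) {
  if (!inherits(spec, "evolution_spec")) stop_mito("`spec` must be an evolution_spec")
  with_seed(spec$seed, {
    state <- spec$start_order
    history <- list()
    for (i in seq_len(spec$n_events)) {
      kind <- sample(names(spec$kind_probs), 1, prob = spec$kind_probs)
      n <- nrow(state)
      draw_segment <- function(min_span = 1L) {
        spans <- min_span:min(spec$max_span, n - 1L)
        s <- if (length(spans) == 1) spans else sample(spans, 1)
        at <- sample(n, 1)
        idx <- ((at - 1L + seq_len(s) - 1L) %% n) + 1L
        state$label[idx]
      }
      evs <- switch(
        kind,
        inversion = {
          seg <- draw_segment()
          list(rearrangement_event("inversion", from = seg[1],
                                   to = seg[length(seg)], polarity = "flip"))
        },
        tdrl = {
          seg <- draw_segment(min_span = 2L)
          keep <- stats::setNames(sample(1:2, length(seg), replace = TRUE), seg)
          list(rearrangement_event("tdrl_translocation", from = seg[1],
                                   to = seg[length(seg)], keep = keep))
        },
        tdnl_rc = list(
          rearrangement_event("whole_genome_duplication"),
          rearrangement_event("polarity_loss", keep = c("+" = 1L, "-" = 2L)),
          rearrangement_event("recombination_join", mode = "3p-3p")
        )
      )
      for (e in evs) state <- apply_event(state, e)
      history <- c(history, evs)
    }
    list(order = state, history = history, start_order = spec$start_order)
  })
}
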