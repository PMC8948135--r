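# The rearrangement operators of the duplication + (non-random/random) loss
# + recombination model family, as pure transformations on signed gene
# orders:
#
#   * whole-genome tandem duplication    (order  -> dimer)
#   * polarity-determined gene loss      (dimer  -> two linear monomers)
#   * random loss of duplicate copies    (dimer  -> order)
#   * 3'-3' recombination join           (pair   -> order)
#   * TDRL segment translocation         (order  -> order)
#   * segment inversion                  (order  -> order)
#
# Every derived object carries an ordered provenance log of the events that
# produced it (see event_history()).

# Circular span of positions from label `from` to label `to`, inclusive,
# traversed in the + reading direction.
og_span_idx <- function(lab, from, to) {
  i <- match(from, lab)
  j <- match(to, lab)
  if (is.na(i)) stop_mito(sprintf("segment start gene '%s' absent", from))
  if (is.na(j)) stop_mito(sprintf("segment end gene '%s' absent", to))
  if (j >= i) i:j else c(i:length(lab), 1:j)
}

append_event <- function(x, e) {
  attr(x, "events") <- c(attr(x, "events") %||% list(), list(e))
  x
}

#' Ordered event provenance of a derived order
#'
#' @param x A `gene_order`, `dimer_order`, or `monomer_pair`.
#' @return A list of [rearrangement_event()] objects, oldest first.
#' @export
event_history <- function(x) attr(x, "events") %||% list()

# ---- duplication -------------------------------------------------------------

#' Tandem duplication of the whole genome
#'
#' Produces a circular dimer: two identical monomer copies covalently linked
#' head to tail, each gene tagged with its copy of origin.  The dimer is
#' linearised (for later loss and joining) at the origin of the input order,
#' so the monomer boundaries sit at the junction preceding the input's first
#' gene.
#'
#' @param x A circular `gene_order`.
#' @return A `dimer_order` tibble with columns `label`, `strand`, `copy`.
#' @export
duplicate_genome <- function(x) {
  assert_gene_order(x)
  n <- nrow(x)
  out <- new_tibble(
    list(label = rep(x$label, 2), strand = rep(x$strand, 2),
         copy = rep(1:2, each = n)),
    nrow = 2L * n, class = "dimer_order"
  )
  attr(out, "anchor") <- attr(x, "anchor")
  attr(out, "events") <- attr(x, "events") %||% list()
  append_event(out, rearrangement_event("whole_genome_duplication"))
}

#' @export
print.dimer_order <- function(x, ...) {
  cat(sprintf("# Circular head-to-tail dimer: 2 x %d genes\n", nrow(x) / 2))
  NextMethod()
}

assert_dimer <- function(x, arg = "x") {
  if (!inherits(x, "dimer_order")) {
    stop_mito(sprintf("`%s` must be a dimer_order (see duplicate_genome())", arg))
  }
  invisible(x)
}

# ---- loss --------------------------------------------------------------------

#' Transcription-polarity determined (non-random) loss
#'
#' Resolves a genome dimer by deleting, from each monomer copy, all genes of
#' one transcriptional polarity: the `keep` rule says which copy retains the
#' genes of each strand (it must be a bijection, so every gene label survives
#' exactly once across the two monomers).  Relative order within each
#' monomer is preserved; the monomers are returned as linear orders.
#'
#' @param d A `dimer_order`.
#' @param keep Named vector mapping strands to copies, e.g.
#'   `c("+" = 1, "-" = 2)` (the default): plus-strand genes survive on
#'   monomer 1, minus-strand genes on monomer 2.
#' @return A `monomer_pair`: list with linear `gene_order`s `monomer1` and
#'   `monomer2`.
#' @export
polarity_loss <- function(d, keep = c("+" = 1, "-" = 2)) {
  assert_dimer(d)
  if (!setequal(names(keep), c("+", "-")) ||
      !setequal(as.integer(keep), 1:2)) {
    stop_mito("`keep` must map the strands '+' and '-' onto copies 1 and 2 bijectively")
  }
  keep <- stats::setNames(as.integer(keep), names(keep))
  monomer <- function(copy) {
    rows <- d$copy == copy & keep[d$strand] == copy
    out <- new_gene_order(d$label[rows], d$strand[rows],
                          anchor = attr(d, "anchor"), circular = FALSE,
                          events = attr(d, "events") %||% list())
    out
  }
  e <- rearrangement_event("polarity_loss", keep = keep)
  m1 <- append_event(monomer(1L), e)
  m2 <- append_event(monomer(2L), e)
  structure(list(monomer1 = m1, monomer2 = m2), class = "monomer_pair")
}

#' @export
print.monomer_pair <- function(x, ...) {
  cat("# Monomer pair after polarity-determined loss\n")
  print(x$monomer1)
  print(x$monomer2)
  invisible(x)
}

#' Random loss of duplicate gene copies
#'
#' From a genome dimer, keeps exactly one copy of every gene, chosen
#' uniformly at random (or as dictated by an explicit `keep` pattern), and
#' returns the surviving genes in dimer order as a circular genome.
#'
#' @param d A `dimer_order`.
#' @param seed Integer seed for the random draw (required unless `keep` is
#'   given).
#' @param keep Optional named vector label -> copy (1 or 2) covering every
#'   gene exactly once.
#' @return A circular `gene_order`.
#' @export
random_loss <- function(d, seed = NULL, keep = NULL) {
  assert_dimer(d)
  labels <- unique(d$label)
  if (is.null(keep)) {
    if (is.null(seed)) stop_mito("random_loss() needs a seed when no explicit `keep` pattern is given")
    keep <- with_seed(seed, stats::setNames(sample(1:2, length(labels), replace = TRUE), labels))
  }
  keep <- validate_keep_pattern(keep, labels)
  rows <- d$copy == keep[d$label]
  out <- new_gene_order(d$label[rows], d$strand[rows],
                        anchor = attr(d, "anchor"), circular = TRUE,
                        events = attr(d, "events") %||% list())
  append_event(out, rearrangement_event("random_loss", keep = keep, seed = seed))
}

validate_keep_pattern <- function(keep, labels) {
  keep <- stats::setNames(as.integer(keep), names(keep))
  missing <- setdiff(labels, names(keep))
  extra <- setdiff(names(keep), labels)
  if (length(missing) > 0) {
    stop_mito(sprintf("loss pattern keeps no copy of: %s",
                      paste(missing, collapse = ", ")))
  }
  if (length(extra) > 0 || anyDuplicated(names(keep))) {
    stop_mito("loss pattern names genes outside the segment, or twice")
  }
  if (!all(keep %in% 1:2)) stop_mito("loss pattern copies must be 1 or 2")
  keep[labels]
}

# ---- recombination join ------------------------------------------------------

#' Join two monomers into one circular genome
#'
#' Under the default `"3p-3p"` mode the 3' end of monomer 1 is ligated to
#' the 3' end of monomer 2 (3' taken with respect to the majority
#' transcription polarity of each monomer's surviving genes): monomer 2's
#' gene sequence is reversed and every one of its genes' transcriptional
#' polarities is flipped, so that when monomer 1 carries the plus-polarity
#' survivors and monomer 2 the minus-polarity survivors the product is
#' single-stranded.  `"head-to-tail"` concatenates without reversal.
#'
#' @param m1,m2 Linear `gene_order` monomers with disjoint label sets
#'   (`m2` may be empty, in which case the result is `m1` circularised), or
#'   a single `monomer_pair` passed as `m1`.
#' @param mode `"3p-3p"` (default) or `"head-to-tail"`.
#' @return A circular `gene_order`.
#' @export
recombination_join <- function(m1, m2 = NULL, mode = c("3p-3p", "head-to-tail")) {
  mode <- match.arg(mode)
  if (inherits(m1, "monomer_pair")) {
    m2 <- m1$monomer2
    m1 <- m1$monomer1
  }
  assert_gene_order(m1, "m1")
  assert_gene_order(m2, "m2")
  if (length(intersect(m1$label, m2$label)) > 0) {
    stop_mito(sprintf("monomers share gene labels: %s",
                      paste(intersect(m1$label, m2$label), collapse = ", ")))
  }
  if (mode == "3p-3p") {
    lab2 <- rev(m2$label)
    str2 <- rev(ifelse(m2$strand == "+", "-", "+"))
  } else {
    lab2 <- m2$label
    str2 <- m2$strand
  }
  out <- new_gene_order(c(m1$label, lab2), c(m1$strand, str2),
                        anchor = attr(m1, "anchor") %||%
                          default_anchor(c(m1$label, lab2)),
                        circular = TRUE,
                        events = attr(m1, "events") %||% list())
  if (!out$label[[1]] %in% c(attr(out, "anchor"))) {
    # keep a valid anchor even if the previous one was lost to the other monomer
    if (!attr(out, "anchor") %in% out$label) {
      attr(out, "anchor") <- default_anchor(out$label)
    }
  }
  append_event(out, rearrangement_event("recombination_join", mode = mode))
}

# ---- TDRL --------------------------------------------------------------------

#' Tandem duplication-random loss translocation
#'
#' Duplicates a contiguous circular segment in tandem and then deletes one
#' copy of each duplicated gene according to `keep` (or a random pattern
#' drawn under `seed`).  Gene content is conserved, no orientation ever
#' changes, and only genes inside the segment can change relative position:
#' the survivors of copy 1 precede the survivors of copy 2 in the segment's
#' place.
#'
#' @param x A circular `gene_order`.
#' @param from,to Labels delimiting the segment (inclusive, traversed in
#'   reading direction).
#' @param keep Named vector label -> copy (1 or 2) covering exactly the
#'   segment's genes; keeping 0 or 2 copies of a gene is an error.
#' @param keep_copy2 Shorthand: labels kept from the second copy, all others
#'   from the first.
#' @param seed Seed for a random pattern when neither `keep` nor
#'   `keep_copy2` is given.
#' @return A circular `gene_order`.
#' @examples
#' o <- gene_order(c("a", "b", "c", "d"), anchor = "a")
#' # move b after c:
#' tdrl_translocate(o, "b", "c", keep_copy2 = "b")$label
#' @export
tdrl_translocate <- function(x, from, to, keep = NULL, keep_copy2 = NULL,
                             seed = NULL) {
  assert_gene_order(x)
  if (!isTRUE(attr(x, "circular"))) stop_mito("TDRL is defined on circular orders")
  u <- og_unpack(x)
  idx <- og_span_idx(u$lab, from, to)
  seg <- u$lab[idx]
  if (!is.null(keep_copy2)) {
    bad <- setdiff(keep_copy2, seg)
    if (length(bad) > 0) {
      stop_mito(sprintf("keep_copy2 genes outside segment: %s",
                        paste(bad, collapse = ", ")))
    }
    keep <- stats::setNames(ifelse(seg %in% keep_copy2, 2L, 1L), seg)
  }
  if (is.null(keep)) {
    if (is.null(seed)) stop_mito("tdrl_translocate() needs `keep`, `keep_copy2`, or a seed")
    keep <- with_seed(seed, stats::setNames(sample(1:2, length(seg), replace = TRUE), seg))
  }
  keep <- validate_keep_pattern(keep, seg)
  # rotate so the segment starts the vector, lay down both tandem copies'
  # survivors, then the untouched remainder
  rot <- og_rotate(u$lab, u$sgn, idx[1])
  s <- length(seg)
  seg_sgn <- rot$sgn[seq_len(s)]
  kept1 <- keep[seg] == 1L
  new_lab <- c(seg[kept1], seg[!kept1], rot$lab[-seq_len(s)])
  new_sgn <- c(seg_sgn[kept1], seg_sgn[!kept1], rot$sgn[-seq_len(s)])
  out <- og_pack(new_lab, new_sgn, x)
  append_event(out, rearrangement_event(
    "tdrl_translocation", from = from, to = to, keep = keep, seed = seed
  ))
}

# ---- inversion ---------------------------------------------------------------

#' Invert a contiguous segment
#'
#' Reverses the order of the genes in the segment and, by default, flips
#' every orientation in it -- the signature of an inversion mediated by the
#' replication machinery.  `flip = FALSE` reverses positions while
#' preserving each gene's transcriptional polarity, modelling a
#' recombination-mediated excision and re-insertion (biologically a
#' transposition-with-reversal; used by the shipped scenario for the
#' trnC-trnQ event, whose product stays single-stranded).
#'
#' @param x A `gene_order`.
#' @param from,to Labels delimiting the segment.
#' @param flip Flip orientations inside the segment (default `TRUE`)?
#' @return A `gene_order` of the same topology.
#' @export
invert_segment <- function(x, from, to, flip = TRUE) {
  assert_gene_order(x)
  u <- og_unpack(x)
  idx <- og_span_idx(u$lab, from, to)
  if (!isTRUE(attr(x, "circular")) && idx[1] > idx[length(idx)]) {
    stop_mito("segment wraps the origin of a linear order")
  }
  lab <- u$lab
  sgn <- u$sgn
  lab[idx] <- rev(lab[idx])
  sgn[idx] <- if (flip) -rev(sgn[idx]) else rev(sgn[idx])
  out <- og_pack(lab, sgn, x)
  append_event(out, rearrangement_event(
    "inversion", from = from, to = to,
    polarity = if (flip) "flip" else "preserve"
  ))
}

# ---- events and dispatch -----------------------------------------------------

event_kinds <- function() {
  c("whole_genome_duplication", "polarity_loss", "random_loss",
    "recombination_join", "inversion", "tdrl_translocation")
}

#' Describe one rearrangement event
#'
#' An algebraic description of a single transformation step, applicable to a
#' matching state with [apply_event()].  Kind-specific parameters:
#' `polarity_loss` takes `keep` (strand -> copy); `random_loss` takes `seed`
#' or `keep`; `recombination_join` takes `mode`; `inversion` takes `from`,
#' `to` and `polarity` (`"flip"` or `"preserve"`); `tdrl_translocation`
#' takes `from`, `to` and `keep`/`keep_copy2`/`seed`.
#'
#' @param kind One of `whole_genome_duplication`, `polarity_loss`,
#'   `random_loss`, `recombination_join`, `inversion`, `tdrl_translocation`.
#' @param ... Kind-specific parameters.
#' @return A `rearrangement_event`.
#' @export
rearrangement_event <- function(kind, ...) {
  kind <- match.arg(kind, event_kinds())
  params <- list(...)
  params <- params[!vapply(params, is.null, TRUE)]
  structure(list(kind = kind, params = params), class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  ps <- if (length(x$params) == 0) "" else {
    paste0("(", paste(names(x$params), collapse = ", "), ")")
  }
  cat(sprintf("<rearrangement_event: %s%s>\n", x$kind, ps))
  invisible(x)
}

#' Apply a rearrangement event to a state
#'
#' Uniform dispatch to the kind-specific operator; errors when the event
#' kind does not match the state kind (e.g. `polarity_loss` on a plain
#' order).  Deterministic events ignore seeds; stochastic events are
#' reproducible given their seed.  Every result carries the event in its
#' provenance log.
#'
#' @param x A `gene_order`, `dimer_order`, or `monomer_pair`.
#' @param e A [rearrangement_event()].
#' @return The transformed state.
#' @export
apply_event <- function(x, e) {
  if (!inherits(e, "rearrangement_event")) {
    stop_mito("`e` must be a rearrangement_event")
  }
  p <- e$params
  mismatch <- function(need) {
    stop_mito(sprintf("event '%s' needs a %s state, got %s",
                      e$kind, need, class(x)[1]),
              class = "mitorearrange_state_error")
  }
  switch(
    e$kind,
    whole_genome_duplication = {
      if (!inherits(x, "gene_order")) mismatch("gene_order")
      duplicate_genome(x)
    },
    polarity_loss = {
      if (!inherits(x, "dimer_order")) mismatch("dimer_order")
      if (is.null(p$keep)) polarity_loss(x) else polarity_loss(x, keep = p$keep)
    },
    random_loss = {
      if (!inherits(x, "dimer_order")) mismatch("dimer_order")
      random_loss(x, seed = p$seed, keep = p$keep)
    },
    recombination_join = {
      if (!inherits(x, "monomer_pair")) mismatch("monomer_pair")
      recombination_join(x, mode = p$mode %||% "3p-3p")
    },
    inversion = {
      if (!inherits(x, "gene_order")) mismatch("gene_order")
      invert_segment(x, p$from, p$to,
                     flip = (p$polarity %||% "flip") == "flip")
    },
    tdrl_translocation = {
      if (!inherits(x, "gene_order")) mismatch("gene_order")
      tdrl_translocate(x, p$from, p$to, keep = p$keep,
                       keep_copy2 = p$keep_copy2, seed = p$seed)
    }
  )
}
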