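# Signed circular gene orders and their algebra: construction, I/O,
# canonical form (rotation + reflection), adjacency sets, and breakpoint
# distance.
#
# Public objects are tibbles (one row per gene, columns `label` and `strand`)
# carrying attributes `anchor`, `circular`, and an event provenance log.
# Hot loops (canonicalisation inside the enumerators, property suites) work
# on plain character/integer vectors via the `og_*` internals.

# ---- internal vector algebra -------------------------------------------------

# Reflection: the same circular molecule read from the opposite strand.
og_reflect <- function(lab, sgn) list(lab = rev(lab), sgn = -rev(sgn))

og_rotate <- function(lab, sgn, i) {
  n <- length(lab)
  if (n == 0 || i == 1) return(list(lab = lab, sgn = sgn))
  idx <- c(i:n, seq_len(i - 1))
  list(lab = lab[idx], sgn = sgn[idx])
}

# Canonical form of a circular signed order: anchor first, anchor on +,
# achieved by rotation and (when the anchor is on -) whole-order reflection.
og_canon <- function(lab, sgn, anchor) {
  i <- match(anchor, lab)
  if (is.na(i)) stop_mito(sprintf("anchor gene '%s' absent from order", anchor))
  if (sgn[i] < 0) {
    r <- og_reflect(lab, sgn)
    lab <- r$lab
    sgn <- r$sgn
    i <- match(anchor, lab)
  }
  og_rotate(lab, sgn, i)
}

og_canon_key <- function(lab, sgn, anchor) {
  cc <- og_canon(lab, sgn, anchor)
  paste(ifelse(cc$sgn > 0, cc$lab, paste0("-", cc$lab)), collapse = " ")
}

# Oriented gene extremities: on +, a gene presents its tail (5') to the left
# and head (3') to the right; on -, the reverse.  An adjacency is the
# unordered pair {right end of gene i, left end of gene i+1}.
og_adjacencies <- function(lab, sgn, circular = TRUE) {
  n <- length(lab)
  if (n == 0) return(character(0))
  right <- ifelse(sgn > 0, paste0(lab, ".h"), paste0(lab, ".t"))
  left  <- ifelse(sgn > 0, paste0(lab, ".t"), paste0(lab, ".h"))
  i <- if (circular) seq_len(n) else seq_len(n - 1)
  j <- if (circular) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
  a <- right[i]
  b <- left[j]
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

og_strand_homogeneity <- function(sgn) {
  if (length(sgn) == 0) return(NA_real_)
  max(sum(sgn > 0), sum(sgn < 0)) / length(sgn)
}

default_anchor <- function(labels) {
  if ("cox1" %in% labels) "cox1" else sort(labels)[1]
}

# ---- class -------------------------------------------------------------------

new_gene_order <- function(label, strand, anchor, circular = TRUE,
                           events = list()) {
  out <- new_tibble(
    list(label = as.character(label), strand = as.character(strand)),
    nrow = length(label),
    class = "gene_order"
  )
  attr(out, "anchor") <- anchor
  attr(out, "circular") <- circular
  attr(out, "events") <- events
  out
}

#' Construct a signed circular gene order
#'
#' A gene order is the circular (or, for monomer intermediates, linear)
#' sequence of genes of a mitochondrial genome together with each gene's
#' transcriptional orientation.  The control region is carried as an ordinary
#' orientable element.  Orders are stored as tibbles with columns `label`
#' and `strand` (`"+"`/`"-"`); the `anchor` attribute fixes the rotation used
#' by [canonicalize()] (by convention `cox1` when present).
#'
#' @param label Character vector of unique gene labels.
#' @param strand Character vector of orientations, `"+"` or `"-"`; recycled
#'   if scalar.
#' @param anchor Label used to fix rotation in canonical form.  Defaults to
#'   `"cox1"` when present, otherwise the lexicographically first label.
#' @param circular Is the order circular?  Monomers produced by
#'   [polarity_loss()] are linear.
#' @return A `gene_order` tibble.
#' @examples
#' gene_order(c("cox1", "trnK", "nad2"), c("+", "+", "-"))
#' @export
gene_order <- function(label, strand = "+", anchor = NULL, circular = TRUE) {
  label <- as.character(label)
  if (length(label) == 0) stop_mito("a gene order needs at least one gene")
  if (any(is.na(label) | label == "")) stop_mito("gene labels must be non-empty")
  if (anyDuplicated(label)) {
    stop_mito(sprintf("duplicated gene labels: %s",
                      paste(unique(label[duplicated(label)]), collapse = ", ")))
  }
  strand <- rep_len(as.character(strand), length(label))
  if (!all(strand %in% c("+", "-"))) {
    stop_mito("strand must be '+' or '-' for every gene")
  }
  anchor <- anchor %||% default_anchor(label)
  new_gene_order(label, strand, anchor = anchor, circular = circular)
}

og_unpack <- function(x) {
  list(lab = x$label, sgn = ifelse(x$strand == "+", 1L, -1L))
}

og_pack <- function(lab, sgn, template, circular = NULL, events = NULL) {
  new_gene_order(
    lab, ifelse(sgn > 0, "+", "-"),
    anchor = attr(template, "anchor") %||% default_anchor(lab),
    circular = circular %||% attr(template, "circular") %||% TRUE,
    events = events %||% attr(template, "events") %||% list()
  )
}

assert_gene_order <- function(x, arg = "x") {
  if (!inherits(x, "gene_order")) {
    stop_mito(sprintf("`%s` must be a gene_order (see gene_order())", arg))
  }
  invisible(x)
}

#' @export
print.gene_order <- function(x, ...) {
  topo <- if (isTRUE(attr(x, "circular"))) "circular" else "linear"
  cat(sprintf("# Signed %s gene order: %d genes, anchor %s\n",
              topo, nrow(x), attr(x, "anchor")))
  cat("# ", paste(ifelse(x$strand == "+", x$label, paste0("-", x$label)),
                  collapse = " "), "\n", sep = "")
  invisible(x)
}

# ---- I/O ---------------------------------------------------------------------

#' Read and write gene-order files
#'
#' The plain-text format holds one gene per line, a leading `-` marking
#' minus-strand orientation, with `#` comment lines ignored.  Round-trips are
#' exact.  `strict = FALSE` skips validation (duplicate labels allowed) so
#' that verbatim literature lists with known anomalies can be loaded for
#' inspection; such objects are plain tibbles, not `gene_order`s.
#'
#' @param path File path.
#' @param anchor,circular Passed to [gene_order()].
#' @param strict Validate labels (default)?
#' @return `read_gene_order()`: a `gene_order` (or, with `strict = FALSE`, a
#'   tibble with columns `label`, `strand`); `write_gene_order()`: `path`,
#'   invisibly.
#' @export
read_gene_order <- function(path, anchor = NULL, circular = TRUE,
                            strict = TRUE) {
  if (!file.exists(path)) stop_mito(sprintf("no such gene-order file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) stop_mito(sprintf("gene-order file is empty: %s", path))
  neg <- startsWith(lines, "-")
  lab <- ifelse(neg, substring(lines, 2), lines)
  strand <- ifelse(neg, "-", "+")
  if (!strict) {
    return(tibble(label = lab, strand = strand))
  }
  gene_order(lab, strand, anchor = anchor, circular = circular)
}

#' @rdname read_gene_order
#' @param x A `gene_order`.
#' @export
write_gene_order <- function(x, path) {
  lines <- ifelse(x$strand == "+", x$label, paste0("-", x$label))
  writeLines(lines, path)
  invisible(path)
}

# ---- operations --------------------------------------------------------------

#' Canonical form of a circular gene order
#'
#' Rotates the order so that the anchor gene comes first and, when the anchor
#' lies on the minus strand, first reflects the whole order (reverse the
#' sequence and flip every orientation) so the anchor is on `+`.  Two circular
#' orders describe the same molecule iff their canonical forms are identical:
#' strand labels on a circular genome are a convention, so canonical form
#' quotients by rotation and reflection.  Idempotent.
#'
#' @param x A circular `gene_order`.
#' @param anchor Anchor label; defaults to the order's anchor attribute.
#' @return The canonical `gene_order`.
#' @export
canonicalize <- function(x, anchor = NULL) {
  assert_gene_order(x)
  if (!isTRUE(attr(x, "circular"))) {
    stop_mito("canonicalize() is defined for circular orders")
  }
  anchor <- anchor %||% attr(x, "anchor")
  u <- og_unpack(x)
  cc <- og_canon(u$lab, u$sgn, anchor)
  out <- og_pack(cc$lab, cc$sgn, x)
  attr(out, "anchor") <- anchor
  out
}

#' Test two gene orders for equality as circular molecules
#'
#' @param a,b `gene_order` objects.
#' @param anchor Optional shared anchor; defaults to `a`'s when present in
#'   both, else the first common label.
#' @return Logical scalar.
#' @export
same_order <- function(a, b, anchor = NULL) {
  assert_gene_order(a, "a")
  assert_gene_order(b, "b")
  if (!setequal(a$label, b$label)) return(FALSE)
  anchor <- anchor %||% shared_anchor(a, b)
  ua <- og_unpack(a)
  ub <- og_unpack(b)
  identical(og_canon_key(ua$lab, ua$sgn, anchor),
            og_canon_key(ub$lab, ub$sgn, anchor))
}

shared_anchor <- function(a, b) {
  common <- intersect(a$label, b$label)
  if (length(common) == 0) stop_mito("orders share no gene labels")
  cand <- attr(a, "anchor")
  if (!is.null(cand) && cand %in% common) cand else sort(common)[1]
}

#' Gene order from an annotation table
#'
#' Genes are taken in ascending start-coordinate order with the annotated
#' strand as orientation; the control region participates as an ordinary
#' element.
#'
#' @param t An annotation table (see [read_annotation()]).
#' @param anchor Anchor for the resulting order (default `cox1` if present).
#' @return A circular `gene_order`.
#' @export
as_gene_order <- function(t, anchor = NULL) {
  assert_annotation(t)
  t <- t[order(t$start), ]
  gene_order(t$name, t$strand, anchor = anchor)
}

#' Oriented adjacency set of a gene order
#'
#' Each gene contributes a tail (5') and a head (3') extremity; an adjacency
#' is the unordered pair of extremities that meet between two neighbouring
#' genes.  A circular n-gene order has exactly n adjacencies; the set is
#' invariant under rotation and reflection.
#'
#' @param x A `gene_order`.
#' @return A tibble with columns `from`, `to`, and the canonical `adjacency`
#'   key.
#' @export
adjacencies <- function(x) {
  assert_gene_order(x)
  u <- og_unpack(x)
  n <- nrow(x)
  circ <- isTRUE(attr(x, "circular"))
  keys <- og_adjacencies(u$lab, u$sgn, circular = circ)
  i <- if (circ) seq_len(n) else seq_len(max(n - 1, 0))
  j <- if (circ) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
  tibble(from = u$lab[i], to = u$lab[j], adjacency = keys)
}

#' Fraction of genes on the majority strand
#'
#' @param x A `gene_order`.
#' @return A number in \[0.5, 1\]; 1 means all genes share one strand.
#' @export
strand_homogeneity <- function(x) {
  assert_gene_order(x)
  og_strand_homogeneity(og_unpack(x)$sgn)
}

#' Breakpoint distance between two circular gene orders
#'
#' The orientation-aware breakpoint distance: the number of gene adjacencies
#' of one order absent from the other, computed on gene extremities so that
#' an in-place single-gene inversion creates two breakpoints.  When the two
#' label sets differ the comparison is restricted to the shared genes (each
#' order projected onto them, preserving relative order) and the report says
#' so.  Symmetric; zero iff the canonical forms agree.
#'
#' @param a,b Circular `gene_order` objects with overlapping label sets.
#' @return A `distance_report`: a list with `breakpoint_distance`,
#'   `shared_adjacencies`, `n_shared_genes`, `restricted`,
#'   `strand_homogeneity_a`, `strand_homogeneity_b`.  [glance()] returns it
#'   as a one-row tibble.
#' @examples
#' a <- read_gene_order(mitorearrange_example("polydesmus_table2.order"))
#' b <- read_gene_order(mitorearrange_example("ancestral_arthropod.order"))
#' glance(order_distance(a, b))
#' @export
order_distance <- function(a, b) {
  assert_gene_order(a, "a")
  assert_gene_order(b, "b")
  shared <- intersect(a$label, b$label)
  if (length(shared) == 0) stop_mito("orders share no gene labels")
  restricted <- !setequal(a$label, b$label)
  pa <- og_unpack(a[a$label %in% shared, ])
  pb <- og_unpack(b[b$label %in% shared, ])
  adj_a <- og_adjacencies(pa$lab, pa$sgn)
  adj_b <- og_adjacencies(pb$lab, pb$sgn)
  shared_adj <- length(intersect(adj_a, adj_b))
  structure(
    list(
      breakpoint_distance = length(shared) - shared_adj,
      shared_adjacencies = shared_adj,
      n_shared_genes = length(shared),
      restricted = restricted,
      strand_homogeneity_a = strand_homogeneity(a),
      strand_homogeneity_b = strand_homogeneity(b)
    ),
    class = "distance_report"
  )
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf(
    "# Gene-order distance over %d shared genes%s\n",
    x$n_shared_genes, if (x$restricted) " (restricted to intersection)" else ""
  ))
  cat(sprintf("breakpoint_distance   %d\n", x$breakpoint_distance))
  cat(sprintf("shared_adjacencies    %d\n", x$shared_adjacencies))
  cat(sprintf("strand_homogeneity    a = %.3f, b = %.3f\n",
              x$strand_homogeneity_a, x$strand_homogeneity_b))
  invisible(x)
}

#' Path to a shipped example file
#'
#' @param file File name under the package's `extdata`; with no argument,
#'   lists the available files.
#' @export
mitorearrange_example <- function(file = NULL) {
  base <- system.file("extdata", package = "mitorearrange")
  if (is.null(file)) return(list.files(base))
  path <- file.path(base, file)
  if (!file.exists(path)) stop_mito(sprintf("no shipped example '%s'", file))
  path
}

#' Shipped reference gene orders
#'
#' `ancestral_myriapod_order()` is the arthropod ancestral ground pattern
#' (the *Limulus* arrangement) used as the starting point of the shipped
#' rearrangement scenario; `polydesmus_order()` is the observed gene order of
#' *Polydesmus* sp. GZCS-2019 read off its annotation table.
#'
#' @return A circular `gene_order`.
#' @export
ancestral_myriapod_order <- function() {
  read_gene_order(mitorearrange_example("ancestral_arthropod.order"))
}

#' @rdname ancestral_myriapod_order
#' @export
polydesmus_order <- function() {
  read_gene_order(mitorearrange_example("polydesmus_table2.order"))
}
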