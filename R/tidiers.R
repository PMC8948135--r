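# broom-style tidy()/glance() methods for the package's result objects.

#' @export
tidy.spacer_report <- function(x, ...) x$records

#' @export
glance.spacer_report <- function(x, ...) {
  tibble(
    n_spacers = x$n_spacers, total_spacer_bp = x$total_spacer_bp,
    min_spacer = x$min_spacer, max_spacer = x$max_spacer,
    n_overlaps = x$n_overlaps, total_overlap_bp = x$total_overlap_bp,
    max_overlap_bp = x$max_overlap_bp, circular_gap = x$circular_gap
  )
}

#' @export
glance.distance_report <- function(x, ...) {
  tibble(
    breakpoint_distance = x$breakpoint_distance,
    shared_adjacencies = x$shared_adjacencies,
    n_shared_genes = x$n_shared_genes,
    restricted = x$restricted,
    strand_homogeneity_a = x$strand_homogeneity_a,
    strand_homogeneity_b = x$strand_homogeneity_b
  )
}

#' @export
tidy.replay_result <- function(x, ...) {
  tibble(
    step = seq_along(x$states) - 1L,
    event = c("(start)", map_chr(x$events, "kind")),
    state = map_chr(x$states, state_kind),
    n_genes = map_int(x$states, state_n_genes),
    strand_homogeneity = x$strand_homogeneity
  )
}

#' @export
glance.replay_result <- function(x, ...) {
  tibble(
    n_events = length(x$events),
    final_state = state_kind(x$final),
    final_match = x$final_match,
    n_mismatches = if (is.null(x$mismatches)) NA_integer_
                   else nrow(x$mismatches),
    final_strand_homogeneity = x$strand_homogeneity[length(x$strand_homogeneity)]
  )
}

#' @export
tidy.gene_order <- function(x, ...) {
  tibble(position = seq_len(nrow(x)), label = x$label, strand = x$strand)
}

#' @export
glance.gene_order <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    circular = isTRUE(attr(x, "circular")),
    anchor = attr(x, "anchor"),
    strand_homogeneity = strand_homogeneity(x),
    n_events = length(event_history(x))
  )
}
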