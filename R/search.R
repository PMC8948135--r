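# Brute-force enumeration of single rearrangement events between two small
# gene orders: every TDRL (segment, loss-pattern) pair within a span bound,
# and every contiguous-segment inversion.  Used to validate the operator
# implementations and to test single-event explanations of observed
# differences.  Candidates are deduplicated by resulting canonical order:
# many loss patterns give one biologically indistinguishable product.

search_candidates <- function(source, target, results, params) {
  anchor <- shared_anchor(source, target)
  ut <- og_unpack(target)
  target_key <- og_canon_key(ut$lab, ut$sgn, anchor)
  keys <- map_chr(results, function(r) og_canon_key(r$lab, r$sgn, anchor))
  keep <- !duplicated(keys)
  tibble(
    !!!params[keep, ],
    result = map(which(keep), function(i) {
      og_pack(results[[i]]$lab, results[[i]]$sgn, source)
    }),
    canonical = keys[keep],
    matches_target = keys[keep] == target_key
  )
}

#' Enumerate single TDRL events between two orders
#'
#' Tries every contiguous circular segment of `source` up to `max_span`
#' genes, duplicated in tandem, with every per-gene loss pattern, and flags
#' the candidates whose product equals `target` as a circular molecule.
#' Candidates are deduplicated by resulting canonical order.  The candidate
#' space grows as `n * sum(2^s)`, so the span bound matters: the default 6
#' keeps exhaustive runs cheap.
#'
#' @param source,target Circular `gene_order`s over the same label set.
#' @param max_span Largest segment length tried (genes).
#' @return A tibble with `from`, `to`, `span`, `pattern` (kept copy per
#'   segment gene, e.g. `"1221"`), the resulting `gene_order` in a `result`
#'   list-column, its `canonical` key, and `matches_target`.
#' @export
enumerate_tdrl <- function(source, target, max_span = 6) {
  assert_gene_order(source, "source")
  assert_gene_order(target, "target")
  check_same_labels(source, target)
  u <- og_unpack(source)
  n <- length(u$lab)
  if (max_span > n) max_span <- n
  if (max_span < 2) stop_mito("max_span must be at least 2")
  rows <- list()
  results <- list()
  k <- 0L
  for (i in seq_len(n)) {
    rot <- og_rotate(u$lab, u$sgn, i)
    for (s in 2:max_span) {
      if (s > n) break
      seg_lab <- rot$lab[seq_len(s)]
      seg_sgn <- rot$sgn[seq_len(s)]
      rest_lab <- rot$lab[-seq_len(s)]
      rest_sgn <- rot$sgn[-seq_len(s)]
      for (mask in 0:(2^s - 1)) {
        kept1 <- bitwAnd(mask, bitwShiftL(1L, seq_len(s) - 1L)) == 0L
        k <- k + 1L
        rows[[k]] <- list(from = seg_lab[1], to = seg_lab[s], span = s,
                          pattern = paste(ifelse(kept1, "1", "2"), collapse = ""))
        results[[k]] <- list(
          lab = c(seg_lab[kept1], seg_lab[!kept1], rest_lab),
          sgn = c(seg_sgn[kept1], seg_sgn[!kept1], rest_sgn)
        )
      }
    }
  }
  params <- bind_rows(map(rows, as_tibble))
  search_candidates(source, target, results, params)
}

#' Enumerate single segment inversions between two orders
#'
#' Applies [invert_segment()] (reverse + flip orientations) to every
#' contiguous circular segment of `source` -- O(n^2) candidates -- and flags
#' those whose product equals `target`.  Deduplicated by resulting canonical
#' order; note that inverting a segment and inverting its circular
#' complement give reflection-equivalent molecules, so they collapse to one
#' candidate.
#'
#' @param source,target Circular `gene_order`s over the same label set.
#' @return A tibble as in [enumerate_tdrl()] (without `pattern`).
#' @export
enumerate_inversions <- function(source, target) {
  assert_gene_order(source, "source")
  assert_gene_order(target, "target")
  check_same_labels(source, target)
  u <- og_unpack(source)
  n <- length(u$lab)
  rows <- list()
  results <- list()
  k <- 0L
  for (i in seq_len(n)) {
    rot <- og_rotate(u$lab, u$sgn, i)
    for (s in seq_len(n)) {
      idx <- seq_len(s)
      lab <- rot$lab
      sgn <- rot$sgn
      lab[idx] <- rev(lab[idx])
      sgn[idx] <- -rev(sgn[idx])
      k <- k + 1L
      rows[[k]] <- list(from = rot$lab[1], to = rot$lab[s], span = s)
      results[[k]] <- list(lab = lab, sgn = sgn)
    }
  }
  params <- bind_rows(map(rows, as_tibble))
  search_candidates(source, target, results, params)
}

check_same_labels <- function(a, b) {
  if (!setequal(a$label, b$label)) {
    stop_mito("source and target must share the same gene label set")
  }
  invisible(TRUE)
}
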