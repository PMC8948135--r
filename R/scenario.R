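# Scenario replay: an ordered list of rearrangement events applied from a
# start order, with every intermediate logged and the final state compared
# (by canonical form) against a target order.  The shipped scenario derives
# the Polydesmus sp. GZCS-2019 gene order from the ancestral arthropod
# arrangement.

#' Build a rearrangement scenario
#'
#' @param start_order Circular `gene_order` the events are applied to.
#' @param events List of [rearrangement_event()] objects, applied in order.
#' @param target_order Optional circular `gene_order` the final state is
#'   verified against.
#' @param expected_intermediates Optional named list mapping step indices
#'   (as character) to `gene_order`s expected after that step.
#' @param name Optional scenario name.
#' @param description Optional free-text description.
#' @return A `rearrangement_scenario`.
#' @export
scenario <- function(start_order, events, target_order = NULL,
                     expected_intermediates = NULL, name = NULL,
                     description = NULL) {
  assert_gene_order(start_order, "start_order")
  if (!is.list(events) ||
      !all(vapply(events, inherits, TRUE, "rearrangement_event"))) {
    stop_mito("`events` must be a list of rearrangement_event objects")
  }
  if (!is.null(target_order)) assert_gene_order(target_order, "target_order")
  structure(
    list(start_order = start_order, events = events,
         target_order = target_order,
         expected_intermediates = expected_intermediates,
         name = name, description = description),
    class = "rearrangement_scenario"
  )
}

#' @export
print.rearrangement_scenario <- function(x, ...) {
  cat(sprintf("# Rearrangement scenario%s: %d genes, %d events%s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$start_order), length(x$events),
              if (is.null(x$target_order)) "" else ", with target"))
  for (i in seq_along(x$events)) {
    cat(sprintf("  %d. %s\n", i, x$events[[i]]$kind))
  }
  invisible(x)
}

state_kind <- function(x) {
  if (inherits(x, "dimer_order")) "dimer" else
    if (inherits(x, "monomer_pair")) "monomer_pair" else
      if (isTRUE(attr(x, "circular"))) "circular_order" else "linear_order"
}

state_n_genes <- function(x) {
  if (inherits(x, "monomer_pair")) nrow(x$monomer1) + nrow(x$monomer2) else nrow(x)
}

state_strand_homogeneity <- function(x) {
  if (inherits(x, "monomer_pair")) {
    sgn <- c(ifelse(x$monomer1$strand == "+", 1L, -1L),
             ifelse(x$monomer2$strand == "+", 1L, -1L))
    og_strand_homogeneity(sgn)
  } else {
    og_strand_homogeneity(ifelse(x$strand == "+", 1L, -1L))
  }
}

#' Replay a rearrangement scenario
#'
#' Applies the scenario's events in order, logging every intermediate state,
#' and (when a target is given) compares the final order to the target by
#' canonical form.  Deterministic given the seeds stored in the events.
#'
#' @param s A [scenario()].
#' @return A `replay_result`: list with `states` (start plus one state per
#'   step), `events`, `final`, `final_match`, `mismatches` (see
#'   [diff_orders()]), `intermediate_match` (per recorded expectation), and
#'   `strand_homogeneity` per step.  [tidy()] gives the per-step log,
#'   [glance()] a one-row summary.
#' @examples
#' res <- replay(polydesmus_scenario())
#' glance(res)
#' @export
replay <- function(s) {
  if (!inherits(s, "rearrangement_scenario")) {
    stop_mito("`s` must be a rearrangement_scenario (see scenario())")
  }
  states <- vector("list", length(s$events) + 1)
  states[[1]] <- s$start_order
  for (i in seq_along(s$events)) {
    states[[i + 1]] <- tryCatch(
      apply_event(states[[i]], s$events[[i]]),
      error = function(cnd) {
        stop_mito(sprintf("event %d (%s) failed: %s",
                          i, s$events[[i]]$kind, conditionMessage(cnd)))
      }
    )
  }
  final <- states[[length(states)]]
  final_match <- NA
  mism <- NULL
  if (!is.null(s$target_order)) {
    if (!inherits(final, "gene_order") || !isTRUE(attr(final, "circular"))) {
      final_match <- FALSE
    } else {
      mism <- diff_orders(final, s$target_order)
      final_match <- nrow(mism) == 0
    }
  }
  inter <- NULL
  if (!is.null(s$expected_intermediates)) {
    inter <- map_lgl(names(s$expected_intermediates), function(k) {
      st <- states[[as.integer(k) + 1]]
      inherits(st, "gene_order") &&
        same_order(st, s$expected_intermediates[[k]])
    })
    names(inter) <- names(s$expected_intermediates)
  }
  structure(
    list(
      states = states,
      events = s$events,
      final = final,
      target = s$target_order,
      final_match = final_match,
      mismatches = mism,
      intermediate_match = inter,
      strand_homogeneity = vapply(states, state_strand_homogeneity, 1)
    ),
    class = "replay_result"
  )
}

#' @export
print.replay_result <- function(x, ...) {
  cat(sprintf("# Replay of %d events\n", length(x$events)))
  print(tidy(x), n = Inf)
  if (!is.na(x$final_match)) {
    cat(sprintf("final_match: %s\n", x$final_match))
    if (!isTRUE(x$final_match) && !is.null(x$mismatches) && nrow(x$mismatches)) {
      cat(sprintf("%d mismatches vs target\n", nrow(x$mismatches)))
    }
  }
  invisible(x)
}

#' Positional differences between two gene orders
#'
#' Both orders are aligned by canonical rotation at a shared anchor (with
#' reflection resolved by the anchor's orientation) and compared position by
#' position.  When the label sets differ, the differences are reported as
#' missing/extra labels instead of positions (duplicated labels in a
#' non-strict tibble input are reported the same way).
#'
#' @param a,b Circular `gene_order` objects (or, for literature lists with
#'   anomalies, plain tibbles with `label`/`strand` columns read via
#'   `read_gene_order(strict = FALSE)`).
#' @param anchor Optional shared anchor label.
#' @return A tibble of mismatches; zero rows iff the canonical forms agree.
#'   Positional rows carry `position`, `expected_label`, `expected_strand`,
#'   `observed_label`, `observed_strand`; label-set rows carry `type`
#'   (`missing`/`extra`, relative to `a`) and `label`.
#' @examples
#' tab <- polydesmus_order()
#' printed <- read_gene_order(mitorearrange_example("final_printed.order"),
#'                            strict = FALSE)
#' diff_orders(tab, printed)  # documents the printed list's anomalies
#' @export
diff_orders <- function(a, b, anchor = NULL) {
  la <- tibble(label = a$label, strand = a$strand)
  lb <- tibble(label = b$label, strand = b$strand)
  if (!setequal(la$label, lb$label) ||
      anyDuplicated(la$label) || anyDuplicated(lb$label)) {
    missing <- setdiff(la$label, lb$label)
    extra <- setdiff(lb$label, la$label)
    dup_a <- unique(la$label[duplicated(la$label)])
    dup_b <- unique(lb$label[duplicated(lb$label)])
    return(bind_rows(
      tibble(type = "missing", label = missing),
      tibble(type = "extra", label = extra),
      tibble(type = "duplicated_in_a", label = dup_a),
      tibble(type = "duplicated_in_b", label = dup_b)
    ))
  }
  anchor <- anchor %||% {
    cand <- attr(a, "anchor") %||% default_anchor(la$label)
    if (cand %in% la$label) cand else default_anchor(la$label)
  }
  ca <- og_canon(la$label, ifelse(la$strand == "+", 1L, -1L), anchor)
  cb <- og_canon(lb$label, ifelse(lb$strand == "+", 1L, -1L), anchor)
  diff <- which(ca$lab != cb$lab | ca$sgn != cb$sgn)
  tibble(
    position = diff,
    expected_label = cb$lab[diff],
    expected_strand = ifelse(cb$sgn[diff] > 0, "+", "-"),
    observed_label = ca$lab[diff],
    observed_strand = ifelse(ca$sgn[diff] > 0, "+", "-")
  )
}

# ---- serialization -----------------------------------------------------------

#' Read and write scenario files
#'
#' Scenarios serialise to JSON: start/target orders either inline (arrays of
#' signed labels, `-` prefix for minus strand) or as paths to gene-order
#' files resolved relative to the scenario file.  Event parameters
#' round-trip exactly.
#'
#' @param path File path.
#' @return `read_scenario()`: a `rearrangement_scenario`;
#'   `write_scenario()`: `path`, invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_mito(sprintf("no such scenario file: %s", path))
  cfg <- jsonlite::read_json(path)
  base <- dirname(path)
  load_order <- function(spec, anchor) {
    if (is.character(spec) && length(spec) == 1) {
      p <- spec
      if (!file.exists(p)) p <- file.path(base, spec)
      read_gene_order(p, anchor = anchor)
    } else {
      lines <- unlist(spec)
      neg <- startsWith(lines, "-")
      gene_order(ifelse(neg, substring(lines, 2), lines),
                 ifelse(neg, "-", "+"), anchor = anchor)
    }
  }
  anchor <- cfg$anchor %||% NULL
  events <- map(cfg$events, function(e) {
    kind <- e$kind
    p <- e[setdiff(names(e), "kind")]
    if (!is.null(p$keep)) p$keep <- unlist(p$keep)
    if (!is.null(p$keep_copy2)) p$keep_copy2 <- unlist(p$keep_copy2)
    if (!is.null(p$seed)) p$seed <- as.integer(p$seed)
    do.call(rearrangement_event, c(list(kind = kind), p))
  })
  scenario(
    start_order = load_order(cfg$start_order, anchor),
    events = events,
    target_order = if (is.null(cfg$target_order)) NULL
                   else load_order(cfg$target_order, anchor),
    name = cfg$name %||% NULL,
    description = cfg$description %||% NULL
  )
}

#' @rdname read_scenario
#' @param s A `rearrangement_scenario`.
#' @export
write_scenario <- function(s, path) {
  if (!inherits(s, "rearrangement_scenario")) {
    stop_mito("`s` must be a rearrangement_scenario")
  }
  signed <- function(o) ifelse(o$strand == "+", o$label, paste0("-", o$label))
  cfg <- list(
    name = s$name,
    description = s$description,
    anchor = attr(s$start_order, "anchor"),
    start_order = signed(s$start_order),
    target_order = if (is.null(s$target_order)) NULL else signed(s$target_order),
    events = map(s$events, function(e) {
      p <- e$params
      if (!is.null(p$keep)) p$keep <- as.list(p$keep)
      c(list(kind = e$kind), p)
    })
  )
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' The shipped Polydesmus sp. GZCS-2019 rearrangement scenario
#'
#' The inferred derivation of the *Polydesmus* sp. GZCS-2019 gene order from
#' the ancestral arthropod arrangement under the whole-genome
#' duplication + polarity-determined/random loss + recombination model:
#' tandem duplication of the entire genome, loss of each gene copy according
#' to its transcriptional polarity, a 3'-3' recombination join that reverses
#' the polarity of the minus-strand monomer (making the genome
#' single-stranded), a TDRL translocation of trnT, and a
#' recombination-mediated, polarity-preserving reversal of trnC-trnQ.
#'
#' @return A `rearrangement_scenario` whose target is the observed gene
#'   order.
#' @export
polydesmus_scenario <- function() {
  read_scenario(mitorearrange_example("polydesmus_scenario.json"))
}
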