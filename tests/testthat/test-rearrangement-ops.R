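# The rearrangement operators: duplication, polarity loss, random loss,
# recombination join, TDRL, inversion, and event dispatch.

test_that("whole-genome duplication yields a tagged head-to-tail dimer", {
  anc <- ancestral_myriapod_order()
  d <- duplicate_genome(anc)
  expect_s3_class(d, "dimer_order")
  expect_equal(nrow(d), 76)
  expect_equal(d$label, rep(anc$label, 2))
  expect_equal(d$strand, rep(anc$strand, 2))
  expect_equal(d$copy, rep(1:2, each = 38))

  single <- duplicate_genome(gene_order("cox1"))
  expect_equal(nrow(single), 2)

  # dropping copy 2 of every gene restores the original order
  keep1 <- stats::setNames(rep(1L, 38), anc$label)
  back <- random_loss(d, keep = keep1)
  expect_true(same_order(back, anc))
})

test_that("polarity loss partitions genes by transcriptional polarity", {
  d <- duplicate_genome(ancestral_myriapod_order())
  mp <- polarity_loss(d, keep = c("+" = 1, "-" = 2))
  # monomer 1 keeps exactly the plus-strand survivors, in ancestral order
  expect_equal(mp$monomer1$label, monomer1_survivors)
  expect_true(all(mp$monomer1$strand == "+"))
  expect_equal(mp$monomer2$label, monomer2_survivors)
  expect_true(all(mp$monomer2$strand == "-"))
  # partition property: union is the full set, intersection empty
  expect_setequal(c(mp$monomer1$label, mp$monomer2$label),
                  ancestral_myriapod_order()$label)
  expect_length(intersect(mp$monomer1$label, mp$monomer2$label), 0)

  # degenerate polarity: everything on one monomer
  flat <- duplicate_genome(gene_order(c("a", "b", "c")))
  mp <- polarity_loss(flat)
  expect_equal(mp$monomer1$label, c("a", "b", "c"))
  expect_equal(nrow(mp$monomer2), 0)

  expect_error(polarity_loss(d, keep = c("+" = 1, "-" = 1)), "bijectively")
})

test_that("random loss keeps exactly one copy per gene, reproducibly", {
  d <- duplicate_genome(random_signed_order(10))
  o1 <- random_loss(d, seed = 5)
  o2 <- random_loss(d, seed = 5)
  expect_equal(as.data.frame(o1), as.data.frame(o2))
  expect_setequal(o1$label, unique(d$label))
  expect_equal(nrow(o1), 10)
  expect_error(random_loss(d), "seed")
  expect_error(random_loss(d, keep = stats::setNames(rep(1, 9),
                                                     unique(d$label)[1:9])),
               "keeps no copy")
})

test_that("the 3'-3' join reverses monomer 2 and flips its polarity", {
  mp <- polarity_loss(duplicate_genome(ancestral_myriapod_order()))
  joined <- recombination_join(mp, mode = "3p-3p")
  expect_true(isTRUE(attr(joined, "circular")))
  # hand-derived expectation: monomer 1 then monomer 2 reversed, all +
  expect_equal(joined$label, post_join_order)
  expect_true(all(joined$strand == "+"))
  expect_equal(strand_homogeneity(joined), 1.0)

  # reading the product from the opposite strand changes nothing
  refl <- gene_order(rev(joined$label),
                     rev(ifelse(joined$strand == "+", "-", "+")),
                     anchor = "cox1")
  expect_true(same_order(joined, refl))

  # an empty monomer 2 just circularises monomer 1
  flat <- polarity_loss(duplicate_genome(gene_order(c("a", "b", "c"))))
  j <- recombination_join(flat)
  expect_equal(j$label, c("a", "b", "c"))

  # overlapping label sets are rejected
  m1 <- gene_order(c("a", "b"), circular = FALSE)
  expect_error(recombination_join(m1, m1), "share gene labels")
})

test_that("head-to-tail join concatenates without reversal", {
  m1 <- gene_order(c("a", "b"), circular = FALSE)
  m2 <- gene_order(c("c", "d"), strand = "-", circular = FALSE)
  j <- recombination_join(m1, m2, mode = "head-to-tail")
  expect_equal(j$label, c("a", "b", "c", "d"))
  expect_equal(j$strand, c("+", "+", "-", "-"))
})

test_that("TDRL relocates trnT into the nad4-trnH junction", {
  joined <- recombination_join(
    polarity_loss(duplicate_genome(ancestral_myriapod_order()))
  )
  after <- tdrl_translocate(joined, "trnT", "nad4", keep_copy2 = "trnT")
  lab <- canonicalize(after)$label
  i <- match("nad4L", lab)
  expect_equal(lab[i:(i + 3)], c("nad4L", "nad4", "trnT", "trnH"))
  # trnT left the trnE/nad6 junction
  expect_equal(lab[match("trnE", lab) + 1], "nad6")
  expect_true(all(after$strand == "+"))
})

test_that("TDRL conserves content, preserves orientation, honours patterns", {
  set.seed(3)
  for (i in 1:50) {
    x <- random_signed_order(sample(5:10, 1))
    n <- nrow(x)
    from <- x$label[sample(n, 1)]
    span <- sample(2:min(4, n - 1), 1)
    to <- x$label[(match(from, x$label) + span - 1 - 1) %% n + 1]
    y <- tdrl_translocate(x, from, to, seed = i)
    expect_setequal(y$label, x$label)
    expect_equal(nrow(y), n)
    # orientations never change under TDRL
    expect_equal(y$strand[match(x$label, y$label)], x$strand)
  }
  # keeping every first copy is the identity
  x <- random_signed_order(8)
  seg <- x$label[2:5]
  y <- tdrl_translocate(x, seg[1], seg[4],
                        keep = stats::setNames(rep(1L, 4), seg))
  expect_true(same_order(x, y))
  # malformed loss patterns: a gene kept twice/zero times
  expect_error(
    tdrl_translocate(x, seg[1], seg[4],
                     keep = stats::setNames(rep(1L, 3), seg[1:3])),
    "keeps no copy"
  )
  expect_error(
    tdrl_translocate(x, seg[1], seg[4],
                     keep = stats::setNames(c(1L, 1L, 2L, 3L), seg)),
    "must be 1 or 2"
  )
})

test_that("inversion reverses a segment and flips its orientations", {
  o <- gene_order(c("trnY", "trnQ", "trnC", "trnI"), anchor = "trnY")
  inv <- invert_segment(o, "trnQ", "trnC")
  expect_equal(inv$label, c("trnY", "trnC", "trnQ", "trnI"))
  expect_equal(inv$strand, c("+", "-", "-", "+"))
  # involution
  back <- invert_segment(inv, "trnC", "trnQ")
  expect_equal(back$label, o$label)
  expect_equal(back$strand, o$strand)
  # inverting the whole circular order is a reflection: canonically equal
  x <- random_signed_order(7)
  whole <- invert_segment(x, x$label[1], x$label[7])
  expect_true(same_order(x, whole))
  # polarity-preserving (recombination-mediated) reversal keeps strands
  pres <- invert_segment(o, "trnQ", "trnC", flip = FALSE)
  expect_equal(pres$label, c("trnY", "trnC", "trnQ", "trnI"))
  expect_equal(pres$strand, rep("+", 4))
})

test_that("inversion and TDRL agree with a brute-force list oracle on all segments", {
  x <- random_signed_order(6)
  lab <- x$label
  sgn <- ifelse(x$strand == "+", 1L, -1L)
  n <- 6L
  for (i in seq_len(n)) {
    for (s in seq_len(n)) {
      idx <- ((i - 1 + seq_len(s) - 1) %% n) + 1
      # oracle: explicit copy, reverse, negate
      exp_lab <- lab
      exp_sgn <- sgn
      exp_lab[idx] <- rev(lab[idx])
      exp_sgn[idx] <- -rev(sgn[idx])
      got <- invert_segment(x, lab[i], lab[idx[s]])
      expect_equal(got$label, exp_lab)
      expect_equal(got$strand, ifelse(exp_sgn > 0, "+", "-"))
    }
  }
})

test_that("apply_event dispatches by kind and enforces state kinds", {
  o <- random_signed_order(6)
  d <- apply_event(o, rearrangement_event("whole_genome_duplication"))
  expect_s3_class(d, "dimer_order")
  expect_error(apply_event(o, rearrangement_event("polarity_loss")),
               class = "mitorearrange_state_error")
  expect_error(apply_event(d, rearrangement_event("inversion", from = "a",
                                                  to = "b")),
               class = "mitorearrange_state_error")
  # stochastic events reproduce under a fixed seed
  e <- rearrangement_event("random_loss", seed = 99L)
  expect_equal(as.data.frame(apply_event(d, e)),
               as.data.frame(apply_event(d, e)))
  # deterministic events ignore seeds entirely
  e1 <- rearrangement_event("inversion", from = o$label[2], to = o$label[3])
  expect_equal(as.data.frame(apply_event(o, e1)),
               as.data.frame(apply_event(o, e1)))
})

test_that("derived orders carry their event provenance", {
  o <- random_signed_order(5)
  d <- duplicate_genome(o)
  j <- recombination_join(polarity_loss(d))
  kinds <- vapply(event_history(j), function(e) e$kind, "")
  expect_equal(kinds, c("whole_genome_duplication", "polarity_loss",
                        "recombination_join"))
})
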