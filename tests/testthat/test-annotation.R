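# Annotation parsing, validation, and the derived spacer/overlap and
# partition statistics.

test_that("the shipped annotation parses to the expected inventory", {
  ann <- polydesmus_annotation()
  expect_s3_class(ann, "mito_annotation")
  expect_equal(nrow(ann), 38)
  expect_equal(genome_length(ann), 15036L)
  counts <- table(ann$category)
  expect_equal(counts[["PCG"]], 13)
  expect_equal(counts[["tRNA"]], 22)
  expect_equal(counts[["rRNA"]], 2)
  expect_equal(counts[["control_region"]], 1)
  # sorted by start, lengths derived from coordinates
  expect_true(!is.unsorted(ann$start))
  expect_equal(ann$length, ann$end - ann$start + 1L)
  expect_equal(ann$length[ann$name == "cox1"], 1533L)
  expect_equal(ann$length[ann$name == "nad1"], 925L)
  expect_true(all(ann$strand == "+"))
})

test_that("parse and validation errors name the offending line or feature", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_annotation(empty), class = "mitorearrange_parse_error")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# genome_length=1000",
               paste(c("name", "category", "start", "end", "strand",
                       "start_codon", "stop_codon", "anticodon"),
                     collapse = "\t"),
               "cox1\tPCG\t1\t300\t+\tATG\tTAA",  # 7 fields
               "cox2\tPCG\t10\t40\t+\tATG\tTAA\t."),
             bad)
  expect_error(read_annotation(bad), "line 3",
               class = "mitorearrange_parse_error")

  expect_error(
    annotation_table(tibble::tibble(
      name = "cox1", category = "PCG", start = 10, end = 5, strand = "+",
      start_codon = "ATG", stop_codon = "TAA"
    ), genome_length = 100),
    "cox1", class = "mitorearrange_validation_error"
  )
  # codons are present iff the feature is protein-coding
  expect_error(
    annotation_table(tibble::tibble(
      name = "trnK", category = "tRNA", start = 1, end = 64, strand = "+",
      start_codon = "ATG", stop_codon = "TAA"
    ), genome_length = 100),
    "trnK", class = "mitorearrange_validation_error"
  )
  expect_error(
    annotation_table(tibble::tibble(
      name = "trnK", category = "rRNA", start = 1, end = 64, strand = "+"
    ), genome_length = 100),
    "inconsistent", class = "mitorearrange_validation_error"
  )
})

test_that("annotation files round-trip exactly", {
  ann <- polydesmus_annotation()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  expect_equal(genome_length(back), genome_length(ann))
})

test_that("spacer/overlap report reproduces the published accounting", {
  rep <- spacer_overlap_report(polydesmus_annotation())
  g <- glance(rep)
  expect_equal(g$n_spacers, 19L)
  expect_equal(g$total_spacer_bp, 351L)
  expect_equal(g$min_spacer, 1L)
  expect_equal(g$max_spacer, 174L)
  expect_equal(g$n_overlaps, 5L)
  expect_equal(g$total_overlap_bp, 27L)
  expect_equal(g$max_overlap_bp, 7L)
  expect_equal(g$circular_gap, 1L)

  # every printed signed intergenic value, keyed by the downstream feature
  printed <- c(cox2 = 3, trnD = 3, atp6 = -4, trnG = 1, nad3 = 7, trnA = 8,
               trnN = 3, trnE = 3, trnS2 = 25, trnV = -3, rrnL = 174,
               trnL1 = 15, trnL2 = 10, nad1 = 1, nad4L = -6, nad4 = -7,
               trnH = 71, nad5 = -7, trnF = 8, trnQ = 2, trnC = 9, trnI = 1,
               trnM = 1, nad2 = 6)
  rec <- tidy(rep)
  lin <- rec[!rec$circular, ]
  expect_equal(stats::setNames(lin$gap[match(names(printed), lin$downstream)],
                               names(printed)),
               printed, ignore_attr = FALSE)
  # all remaining junctions abut exactly
  expect_true(all(lin$gap[!lin$downstream %in% names(printed)] == 0))

  # the five overlapping pairs, with the two 7-bp overlaps as derived from
  # coordinates (nad4L/nad4 and trnH/nad5)
  ovl <- lin[lin$gap < 0, ]
  expect_setequal(paste(ovl$upstream, ovl$downstream),
                  c("atp8 atp6", "rrnS trnV", "trnP nad4L", "nad4L nad4",
                    "trnH nad5"))
  expect_setequal(ovl$downstream[ovl$gap == -7], c("nad4", "nad5"))
})

test_that("signed gaps conserve the genome length on any valid table", {
  for (ann in list(polydesmus_annotation(), toy_annotation())) {
    rec <- tidy(spacer_overlap_report(ann))
    expect_equal(sum(rec$gap) + sum(ann$length), genome_length(ann))
  }
})

test_that("abutting features yield gap zero, neither spacer nor overlap", {
  ann <- annotation_table(
    tibble::tibble(name = c("rrnS", "rrnL"), category = "rRNA",
                   start = c(1L, 101L), end = c(100L, 200L), strand = "+"),
    genome_length = 200
  )
  rep <- spacer_overlap_report(ann)
  expect_equal(tidy(rep)$gap[1], 0L)
  expect_equal(rep$n_spacers, 0L)
  expect_equal(rep$n_overlaps, 0L)
})

test_that("partition lengths match the published partition table", {
  pl <- partition_lengths(polydesmus_annotation())
  expect_equal(pl$total_bp[pl$category == "PCG"], 10997L)
  expect_equal(pl$total_bp[pl$category == "tRNA"], 1415L)
  expect_equal(pl$total_bp[pl$category == "rRNA"], 1862L)
  expect_equal(pl$total_bp[pl$category == "control_region"], 437L)
})

test_that("partition lengths are invariant under input row order", {
  ann <- polydesmus_annotation()
  shuffled <- annotation_table(
    as.data.frame(ann)[sample(nrow(ann)), ], genome_length(ann)
  )
  expect_equal(partition_lengths(shuffled), partition_lengths(ann))
  # single feature: total is its length
  single <- annotation_table(
    tibble::tibble(name = "rrnS", category = "rRNA", start = 5, end = 54,
                   strand = "+"),
    genome_length = 60
  )
  pl <- partition_lengths(single)
  expect_equal(pl$total_bp, 50L)
})

test_that("codon inventory reads starts and truncated stops off the genome", {
  g <- synth_genome(polydesmus_genome_spec(seed = 7))
  ci <- codon_inventory(g$annotation, g$sequence)
  ann <- g$annotation
  pcgs <- ann[ann$category == "PCG", ]
  expect_setequal(ci$gene, pcgs$name)
  # every annotated start/stop is realised in the synthetic sequence
  expect_equal(ci$start_codon[match(pcgs$name, ci$gene)], pcgs$start_codon)
  expect_equal(ci$stop_codon[match(pcgs$name, ci$gene)], pcgs$stop_codon)
  expect_equal(ci$start_codon[ci$gene == "nad2"], "GTG")
  expect_equal(sum(ci$stop_class == "T"), 6L)

  # minimal complete gene, and the too-short error
  mini <- annotation_table(
    tibble::tibble(name = "atp8", category = "PCG", start = 1, end = 6,
                   strand = "+", start_codon = "ATG", stop_codon = "TAA"),
    genome_length = 6
  )
  expect_equal(codon_inventory(mini, "ATGTAA")$stop_codon, "TAA")
  tiny <- annotation_table(
    tibble::tibble(name = "atp8", category = "PCG", start = 1, end = 5,
                   strand = "+", start_codon = "ATG", stop_codon = "TA"),
    genome_length = 5
  )
  expect_error(codon_inventory(tiny, "ATGTA"), "shorter than 6")
})

test_that("minus-strand features are reverse-complemented before reading", {
  ann <- annotation_table(
    tibble::tibble(name = "nad5", category = "PCG", start = 1, end = 9,
                   strand = "-", start_codon = "ATG", stop_codon = "TAA"),
    genome_length = 9
  )
  # revcomp("TTACATCAT") = ATGATGTAA
  ci <- codon_inventory(ann, "TTACATCAT")
  expect_equal(ci$start_codon, "ATG")
  expect_equal(ci$stop_codon, "TAA")
  expect_equal(unname(feature_sequences(ann, "TTACATCAT")), "ATGATGTAA")
})
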