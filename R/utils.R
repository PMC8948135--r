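# Internal helpers shared across modules.

# Controlled vocabulary for mitochondrial gene labels: 13 protein-coding
# genes, 2 rRNAs, 22 tRNAs (Ser and Leu each with two isoacceptors), and the
# control region.
mito_pcg_names <- function() {
  c("cox1", "cox2", "cox3", "nad1", "nad2", "nad3", "nad4", "nad4L",
    "nad5", "nad6", "atp6", "atp8", "cob")
}

mito_trna_names <- function() {
  paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
                  "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"))
}

mito_gene_names <- function() {
  c(mito_pcg_names(), "rrnS", "rrnL", mito_trna_names(), "CR")
}

# Category implied by a label's prefix; used to cross-check annotations.
category_for_name <- function(name) {
  dplyr::case_when(
    name %in% mito_pcg_names() ~ "PCG",
    str_detect(name, "^trn") ~ "tRNA",
    str_detect(name, "^rrn") ~ "rRNA",
    name == "CR" ~ "control_region",
    TRUE ~ NA_character_
  )
}

mito_categories <- function() c("PCG", "tRNA", "rRNA", "control_region")

# Run `code` under a caller-supplied seed without disturbing the global RNG
# stream; seeds are mandatory wherever results must be reproducible.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

stop_mito <- function(msg, class = "mitorearrange_error") {
  abort(msg, class = class)
}
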