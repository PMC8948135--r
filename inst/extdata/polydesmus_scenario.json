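{
  "name": "polydesmus_gzcs2019_td_nrl_rc",
  "description": "Derivation of the Polydesmus sp. GZCS-2019 gene order from the ancestral arthropod arrangement under the TD(N\\R)L + RC model: whole-genome tandem duplication, transcription-polarity determined loss, 3'-3' recombination join (which reverses the polarity of the minus-strand monomer), a TDRL translocation of trnT, and a recombination-mediated, polarity-preserving reversal of trnC-trnQ.",
  "anchor": "cox1",
  "start_order": "ancestral_arthropod.order",
  "target_order": "polydesmus_table2.order",
  "events": [
    { "kind": "whole_genome_duplication" },
    { "kind": "polarity_loss", "keep": { "+": 1, "-": 2 } },
    { "kind": "recombination_join", "mode": "3p-3p" },
    { "kind": "tdrl_translocation", "from": "trnT", "to": "nad4", "keep_copy2": ["trnT"] },
    { "kind": "inversion", "from": "trnC", "to": "trnQ", "polarity": "preserve" }
  ]
}
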