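# The "ultimate gene arrangement" after the 3'-3' recombination join, verbatim
# as printed in the source description.  "+" lines were printed as plus-strand,
# "-" lines as minus-strand (the text adds that the polarity of the
# minus-strand block is reversed by the join, making the molecule
# single-stranded).
# KNOWN ANOMALIES (preserved): nad4L appears twice and nad1 is absent (the
# first nad4L, after trnL2, must be nad1); the list also places trnT between
# nad4 and trnH and trnY between trnF and trnQ, i.e. it already incorporates
# the TDRL and recombination-reversal events.  The coordinate-derived gene
# order (polydesmus_table2.order) is the verification target, not this list.
# Read with strict = FALSE.
trnI
trnM
nad2
trnW
cox1
cox2
trnK
trnD
atp8
atp6
cox3
trnG
nad3
trnA
trnR
trnN
trnS1
trnE
nad6
cob
trnS2
CR
-rrnS
-trnV
-rrnL
-trnL1
-trnL2
-nad4L
-trnP
-nad4L
-nad4
-trnT
-trnH
-nad5
-trnF
-trnY
-trnQ
-trnC
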