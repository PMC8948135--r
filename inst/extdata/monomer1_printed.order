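# Monomer 1 of the genome dimer as printed in the source description, verbatim.
# "-" = minus-strand gene; in this monomer every minus-strand gene is the one
# deleted by polarity-determined loss, so the survivors are the "+" lines.
# KNOWN ANOMALY (preserved): the entry between trnS2 and trnL2 is printed as
# nad4L, duplicating nad4L and omitting nad1; the coordinate-derived gene
# order shows nad1 must stand there.  Read with strict = FALSE.
trnI
-trnQ
trnM
nad2
trnW
-trnC
-trnY
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
-trnF
-nad5
-trnH
-nad4
-nad4L
trnT
-trnP
nad6
cob
trnS2
-nad4L
-trnL2
-trnL1
-rrnL
-trnV
-rrnS
CR
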