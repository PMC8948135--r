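# Monomer 2 of the genome dimer as printed in the source description, verbatim,
# in its printed (reverse) reading direction.  "+" lines are the plus-strand
# genes, i.e. the copies deleted from this monomer; the "-" lines survive.
# KNOWN ANOMALIES (preserved): trnY is missing entirely (37 entries instead of
# 38), and nad4L is again printed where nad1 must stand (between trnL2 and
# trnS2 in this reading).  Read with strict = FALSE.
CR
-rrnS
-trnV
-rrnL
-trnL1
-trnL2
-nad4L
trnS2
cob
nad6
-trnP
trnT
-nad4L
-nad4
-trnH
-nad5
-trnF
trnE
trnS1
trnN
trnR
trnA
nad3
trnG
cox3
atp6
atp8
trnD
trnK
cox2
cox1
-trnC
trnW
nad2
trnM
-trnQ
trnI
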