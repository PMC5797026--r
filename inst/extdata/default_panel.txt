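# Default NK-AML driver gene panel: genes named in the source cohort.
# Replace with the full targeted panel for real data.
[drivers]
NPM1
FLT3
DNMT3A
IDH1
IDH2
NRAS
TET2
CEBPA
TP53
[chromatin_spliceosome]
RUNX1
ASXL1
BCOR
STAG2
EZH2
SRSF2
SF3B1
U2AF1
ZRSR2
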