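# SYNTHETIC placeholder panel: 71 gene symbols standing in for a
# user-supplied EphA2-signaling-cascade gene set. Replace with your own
# curated list (one symbol per line) for real analyses.
EPHA2
EFNA1
SRC
FYN
YES1
PTK2
PXN
BCAR1
CRK
CRKL
RHOA
RHOB
RHOC
RAC1
RAC2
CDC42
ROCK1
ROCK2
LIMK1
LIMK2
CFL1
ARHGEF1
ARHGEF7
ARHGAP5
VAV1
VAV2
VAV3
TIAM1
PAK1
PAK2
PAK4
WASF1
WASF2
WASL
ARPC2
ARPC3
ACTR2
ACTR3
ACTB
ACTG1
MYH9
MYH10
MYL9
MYLK
TLN1
VCL
ZYX
ACTN1
ACTN4
FLNA
FLNB
CTTN
CORO1C
GSN
TPM1
TPM4
CAV1
CAV2
ITGB1
ITGA5
FN1
SDC1
GRB2
SHC1
SOS1
PIK3CA
PIK3R1
AKT1
PTEN
MAPK1
MAPK3
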