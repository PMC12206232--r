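SRY
RPS4Y1
ZFY
AMELY
TBL1Y
PRKY
USP9Y
DDX3Y
UTY
TMSB4Y
NLGN4Y
KDM5D
EIF1AY
TXLNGY
RPS4Y2
TSPY1
RBMY1A1
DAZ1
HSFY1
CDY1
BPY2
PRY
VCY
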