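name,role,measured,perturbable,constitutive
IL6,stimulus,FALSE,FALSE,FALSE
gp130,signaling,FALSE,FALSE,FALSE
JAK1,signaling,FALSE,FALSE,FALSE
STAT3,signaling,FALSE,TRUE,FALSE
SHP2,signaling,FALSE,FALSE,FALSE
RAS,signaling,FALSE,FALSE,FALSE
RAF1,signaling,FALSE,FALSE,FALSE
MEK,signaling,FALSE,FALSE,FALSE
ERK,signaling,FALSE,TRUE,FALSE
PI3K,signaling,FALSE,TRUE,FALSE
AKT,signaling,FALSE,FALSE,FALSE
IKK,signaling,FALSE,FALSE,FALSE
NFKB,transcription_factor,FALSE,FALSE,FALSE
RXRNR,complex,FALSE,FALSE,FALSE
GR,transcription_factor,FALSE,FALSE,FALSE
AHR,transcription_factor,FALSE,FALSE,FALSE
HNF1A,transcription_factor,FALSE,FALSE,TRUE
HNF4A,transcription_factor,FALSE,FALSE,TRUE
SOCS1,signaling,FALSE,FALSE,FALSE
SOCS3,gene,TRUE,FALSE,FALSE
CRP,gene,TRUE,FALSE,FALSE
SAA1,gene,TRUE,FALSE,FALSE
CYP3A4,gene,TRUE,FALSE,FALSE
CYP2C8,gene,TRUE,FALSE,FALSE
CYP2C9,gene,TRUE,FALSE,FALSE
CYP2C19,gene,TRUE,FALSE,FALSE
CYP2B6,gene,TRUE,FALSE,FALSE
CYP1A2,gene,TRUE,FALSE,FALSE
CYP2A6,gene,TRUE,FALSE,FALSE
CYP2D6,gene,TRUE,FALSE,FALSE
CYP2E1,gene,TRUE,FALSE,FALSE
CYP1A1,gene,TRUE,FALSE,FALSE
ABCB1,gene,TRUE,FALSE,FALSE
ABCC2,gene,TRUE,FALSE,FALSE
ABCG2,gene,TRUE,FALSE,FALSE
SLCO1B1,gene,TRUE,FALSE,FALSE
SLC10A1,gene,TRUE,FALSE,FALSE
UGT1A1,gene,TRUE,FALSE,FALSE
UGT2B7,gene,TRUE,FALSE,FALSE
GSTA1,gene,TRUE,FALSE,FALSE
SULT1A1,gene,TRUE,FALSE,FALSE
NAT1,gene,TRUE,FALSE,FALSE
NAT2,gene,TRUE,FALSE,FALSE
ALB,gene,TRUE,FALSE,FALSE
TTR,gene,TRUE,FALSE,FALSE
TSC22D3,gene,TRUE,FALSE,FALSE
PER1,gene,TRUE,FALSE,FALSE
PPARA,gene,TRUE,FALSE,FALSE
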