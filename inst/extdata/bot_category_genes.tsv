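gene	category
IL6	immune_inflammatory
CCR2	immune_inflammatory
IFNG	membrane_transporter
ATP1B1	membrane_transporter
GAS6	membrane_transporter
PSEN1	membrane_transporter
CTNNB1	cycle_signaling
GATA3	cycle_signaling
IL1B	cycle_signaling
AKT1	metabolism
SIRT1	metabolism
IL4	metabolism
PDGFB	metabolism
MAPK3	metabolism
SRC	metabolism
TWIST1	metabolism
TGFB1	metabolism
ADIPOQ	metabolism
PPARGC1A	metabolism
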