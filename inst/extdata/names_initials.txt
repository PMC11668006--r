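# Short name tokens (<= 3 characters): initials and very short given
# names, one per line. Each entry is a single alphanumeric run so it
# tokenizes as exactly one token.
SB
JB
KL
MW
AN
RP
TH
GC
DV
EJ
Jo
Al
Raj
Ali
Ben
Sam
Lee
Ana
Kim
Mia
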