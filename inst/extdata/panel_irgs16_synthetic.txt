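# Synthetic stand-in for the 16-gene iron regulatory gene signature (IRGS).
# The published signature is not available in machine-readable form; this
# curated reconstruction keeps the constraints the analysis relies on
# (contains HFE, TFRC, SFXN1 and SLC25A37; subset of the 61-gene panel).
HFE
TFRC
TFR2
TF
SFXN1
SLC25A37
SLC40A1
HAMP
HMOX1
FTH1
FTL
ACO1
IREB2
CYBRD1
SLC11A2
STEAP3
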