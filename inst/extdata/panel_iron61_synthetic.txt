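# Synthetic stand-in for the 61-gene iron metabolism panel. The published
# list is not enumerated in a machine-readable source; this curated set
# covers iron uptake, transport, storage, export, heme synthesis and
# iron-sulfur cluster assembly, and contains the shipped 16-gene IRGS
# stand-in and the eight-gene signature.
HFE
TFRC
TFR2
TF
FTL
FTH1
FTMT
SLC11A2
SLC40A1
HAMP
HFE2
TMPRSS6
STEAP1
STEAP2
STEAP3
STEAP4
CYBRD1
ACO1
IREB2
SLC25A37
SLC25A28
FXN
ABCB7
ABCB6
ISCU
NFS1
GLRX5
HMOX1
HMOX2
BLVRA
BLVRB
ALAS1
ALAS2
ALAD
HMBS
UROS
UROD
CPOX
PPOX
FECH
SFXN1
SFXN2
SFXN3
SFXN4
SFXN5
LTF
LCN2
CP
HEPH
SLC39A14
SLC39A8
SLC46A1
SLC48A1
FLVCR1
FLVCR2
ABCG2
SCARA5
NDFIP1
EPAS1
HIF1A
B2M
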