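# Default cis-regulatory element table. The A-box, C-box and G-box sequences
# are the canonical ACGT-core boxes; all other pattern strings are this
# package's transcription of the public PlantCARE consensus and are editable
# configuration, not authoritative ground truth.
name	pattern	category
CAAT-box	CCAAT	core
A-box	TACGTA	development
CAT-box	GCCACT	development
HD-Zip1	CAATWATTG	development
ABRE	ACGTG	hormone
AuxRR-core	GGTCCAT	hormone
CGTCA-motif	CGTCA	hormone
TGA-element	AACGAC	hormone
GARE-motif	TCTGTTG	hormone
G-box	CACGTG	hormone
C-box	GACGTC	core
TCA-element	CCATCTTTTT	hormone
AE-box	AGAAACAA	stress
ARE	AAACCA	stress
Box4	ATTAAT	stress
LTR	CCGAAA	stress
MBS	CAACTG	stress
TC-rich	ATTTTCTTCA	stress
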