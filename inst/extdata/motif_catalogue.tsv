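name	pattern	reference
ABRE-like element	ACGTGKC	PLACE
ACGT element, G-box	CACGTG	PLACE
ATHB6 core element	CAATTATTA	PLACE
CRT/DRE-like motif	DRCCGACNW	PLACE
Coupling element 3-like	ACGCGTGTCCTC	AGRIS
Evening element	AAAATATCT	PLACE
PIATGAPB element	GTGATCAC	PLACE
TCA1 motif-like	TCATCTTCTT	PLACE
W-box	TTGACC	PLACE
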