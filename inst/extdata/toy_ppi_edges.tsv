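protein1	protein2	combined_score
DEGS1_toy	SCD_toy	820
DEGS1_toy	ELOVL5_toy	640
SQLE_toy	FDFT1_toy	910
PISD_toy	PEMT_toy	760
ACACA_toy	FASN_toy	980
CPT1A_toy	CPT2_toy	700
PFK_toy	CS_toy	450
PTEN_toy	PISD_toy	300
NDUFA_toy	NDUFB_toy	990
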