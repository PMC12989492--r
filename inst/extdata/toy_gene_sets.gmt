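sphingolipid_toy	toy sphingolipid enzymes	DEGS1_toy	SCD_toy	ELOVL5_toy
cholesterol_toy	toy cholesterol enzymes	SQLE_toy	FDFT1_toy
phospholipid_toy	toy phospholipid enzymes	PISD_toy	PEMT_toy	PTEN_toy
energy_core_toy	toy core energy genes	PFK_toy	CS_toy	PDH_toy	NDUFA_toy	NDUFB_toy	ACACA_toy	FASN_toy	CPT1A_toy	CPT2_toy	PANK_toy	VNN_toy	NADS_toy
decoy_toy	unrelated filler genes	filler_001	filler_002	filler_003	filler_004	filler_005
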