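structure_id	site_name	chain_id	residue_number	expected_aa
dmel_synthetic	pocket_5prime	A	701	Y
dmel_synthetic	pocket_5prime	A	702	Y
dmel_synthetic	pocket_5prime	A	703	Y
dmel_synthetic	pocket_5prime	A	704	Y
dmel_synthetic	pocket_3prime	A	801	Y
dmel_synthetic	pocket_3prime	A	802	Y
dmel_synthetic	pocket_3prime	A	803	Y
dmel_synthetic	pocket_3prime	A	804	Y
dmel_synthetic	RIII_A	A	1201	E
dmel_synthetic	RIII_A	A	1202	E
dmel_synthetic	RIII_A	A	1203	E
dmel_synthetic	RIII_A	A	1204	E
dmel_synthetic	RIII_B	A	1401	D
dmel_synthetic	RIII_B	A	1402	D
dmel_synthetic	RIII_B	A	1403	D
dmel_synthetic	RIII_B	A	1404	D
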