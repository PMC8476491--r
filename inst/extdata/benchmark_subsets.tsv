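dataset	description	n_deleterious	n_benign
HumVar	disease-causing vs common variants	1230	1230
UniFun	functional-assay variants from UniProt	25	25
BRCA1-DMS	deep mutational scanning, homology-directed repair	41	41
TP53-TA	transactivation assay	413	413
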