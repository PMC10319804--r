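Gene_name	Matrix_id	Motif	Organism
ELAVL1	SM001	ATTTTTA	Homo_sapiens
HNRNPC	SM002	ATTTTTA	Homo_sapiens
KHSRP	SM003	TGTGTG	Homo_sapiens
SRSF1	SM004	GGAGGA	Homo_sapiens
NOVA1	SM005	TCATT	Homo_sapiens
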