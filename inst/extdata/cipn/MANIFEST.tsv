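file	md5
studies.tsv	a7fd2c3c8b5b19bc99752d9f1ecd3c4e
agent_gene_matrix.tsv	75152df411c05a95a5d6191d46077bc7
focus_genes.gmt	a913d44f6b6dc13c9f0883328a952b3c
hubs_platinum.tsv	178361325c0f868840a3aeb82a19f828
hubs_platinum_taxane.tsv	0e2c8c0f8834e9900f29b290da154650
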