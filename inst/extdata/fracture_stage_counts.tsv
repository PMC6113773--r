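# Case and control totals of the fracture GWAS stages.
stage	n_cases	n_controls
discovery	37857	227116
replication	147200	150085
combined	185057	377201
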