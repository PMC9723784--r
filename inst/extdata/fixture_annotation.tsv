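# Toy per-genome gene counts for the worked example (illustrative values,
# not measurements).
genome_id	enzyme_id	gene_count
MAG1	vanillate_monooxygenase	2
MAG1	muconate_cycloisomerase	1
MAG1	benzoate_dioxygenase	2
MAG1	catechol_dioxygenase	1
MAG1	protocatechuate_dioxygenase	1
MAG1	oxoadipate_transferase	2
MAG4	hydroxybenzoate_monooxygenase	1
MAG4	salicylate_hydroxylase	1
MAG4	muconate_cycloisomerase	1
MAG5	catechol_dioxygenase	1
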