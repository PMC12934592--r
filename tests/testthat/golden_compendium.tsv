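# redoxmap 0.1.0
pair_id	mouse_position	human_position	n_conditions	delta	redox_class	domains	protein_classes	structure_ids
P1	3	3	2	30	dynamic	SH2	kinase	2B3O
P1	9	9	2	5	stable		kinase	2B3O
P2	3	5	2	10	stable		phosphatase	
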