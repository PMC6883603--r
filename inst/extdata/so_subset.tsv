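term_id	name	parent_ids	ontology_key
SO:0001060	sequence_variant		sequence
SO:0001576	transcript_variant	SO:0001060	sequence
SO:0001968	coding_transcript_variant	SO:0001576	sequence
SO:0001818	protein_altering_variant	SO:0001968	sequence
SO:0001583	missense_variant	SO:0001818	sequence
SO:0001587	stop_gained	SO:0001818	sequence
SO:0001589	frameshift_variant	SO:0001818	sequence
SO:0001821	inframe_insertion	SO:0001818	sequence
SO:0001822	inframe_deletion	SO:0001818	sequence
SO:0001819	synonymous_variant	SO:0001968	sequence
SO:0001627	intron_variant	SO:0001576	sequence
SO:0001623	5_prime_UTR_variant	SO:0001576	sequence
SO:0001624	3_prime_UTR_variant	SO:0001576	sequence
SO:0001629	splice_site_variant	SO:0001576	sequence
SO:0001574	splice_acceptor_variant	SO:0001629	sequence
SO:0001575	splice_donor_variant	SO:0001629	sequence
SO:0001537	structural_variant	SO:0001060	sequence
SO:0001565	gene_fusion	SO:0001537	sequence
SO:0001886	transcript_fusion	SO:0001537	sequence
SO:0001880	feature_amplification	SO:0001537	sequence
SO:0001019	copy_number_variation	SO:0001537	sequence
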