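quantity	numerator	denominator
pathogenic_in_ppi_network	124	1484
pathogenic_in_all_communities	63	496
pathogenic_in_relevant_communities	22	84
drive_detected_consensus	1300	1842
drive_flagged_of_detected_consensus	54	1300
drive_detected_relevant_communities	79	84
drive_flagged_of_detected_relevant_communities	5	79
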