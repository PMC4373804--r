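species	archipelago	n_islands_occupied	n_archipelago_islands	n_haplotypes	inferred_events
Buteo galapagoensis	Galapagos	10	12	7	9
Cistus monspeliensis	Canaries	5	7	10	7
Juniperus brevifolia	Azores	8	9	16	19
Olea europaea subsp. guanchica	Canaries	4	4	11	11
Picconia azorica	Azores	7	9	5	10
Setophaga petechia	Galapagos	9	12	8	10
Xylocopa darwini	Galapagos	9	12	12	10
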