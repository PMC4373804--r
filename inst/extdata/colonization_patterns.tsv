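species_group	n_islands_occupied	pattern
Bulimulus land snails	7	diverged early on southeastern islands, then spread northwest
Buteo hawk	11	recent western arrival, rapid expansion, then per-island isolation
Chelonoidis tortoises	9	early central-western divergence with recurrent inter-island movement
Galagete moths	12	radiation tracking island emergence, extensive colonization of all islands
Galapaganus weevils	9	early arrival on young Isabela, deviations from sequential volcano colonization
Microlophus lizards	12	early split into eastern and western lineages
Mimus mockingbirds	12	northward colonization from southern islands
Phyllodactylus geckos	10	ancient arrival predating current islands, central-northern spread plus an independent eastern colonization
Setophaga warbler	8	arrival on central islands then spread across the archipelago, medium migration success
Xylocopa bee	9	early arrival on a central-western island, secondary eastern colonization, little migration since
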