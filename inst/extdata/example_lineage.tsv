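taxid	superkingdom	kingdom	phylum	class	order	family	genus	species
6183	Eukaryota	Metazoa	Platyhelminthes	Trematoda	Diplostomida	Schistosomatidae	Schistosoma	Schistosoma mansoni
6239	Eukaryota	Metazoa	Nematoda	Chromadorea	Rhabditida	Rhabditidae	Caenorhabditis	Caenorhabditis elegans
8521	Eukaryota	Metazoa	Chordata	Lepidosauria	Squamata	Xantusiidae	Xantusia	Xantusia vigilis
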