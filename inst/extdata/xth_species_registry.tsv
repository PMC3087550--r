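species_code	full_name	lineage_path	genome_complete
At	Arabidopsis thaliana	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Euphyllophyta;Spermatophyta;Angiosperms;Eudicots	yes
Gm	Glycine max	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Euphyllophyta;Spermatophyta;Angiosperms;Eudicots	yes
Pt	Populus trichocarpa	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Euphyllophyta;Spermatophyta;Angiosperms;Eudicots	yes
Vv	Vitis vinifera	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Euphyllophyta;Spermatophyta;Angiosperms;Eudicots	yes
Os	Oryza sativa	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Euphyllophyta;Spermatophyta;Angiosperms;Monocots	yes
Sb	Sorghum bicolor	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Euphyllophyta;Spermatophyta;Angiosperms;Monocots	yes
Pin	Pinus spp.	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Euphyllophyta;Spermatophyta;Gymnosperms	no
Pic	Picea spp.	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Euphyllophyta;Spermatophyta;Gymnosperms	no
Sm	Selaginella moellendorffii	Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Lycophyta	yes
Pp	Physcomitrella patens	Viridiplantae;Streptophyta;Embryophyta;Bryophyta	yes
Tr	Tortula ruralis	Viridiplantae;Streptophyta;Embryophyta;Bryophyta	no
Mp	Marchantia polymorpha	Viridiplantae;Streptophyta;Embryophyta;Marchantiophyta	no
Cv	Chara vulgaris	Viridiplantae;Streptophyta;Charophyceae	no
Cp	Closterium peracerosum	Viridiplantae;Streptophyta;Zygnemophyceae	no
Ot	Ostreococcus tauri	Viridiplantae;Chlorophyta	yes
Ol	Ostreococcus lucimarinus	Viridiplantae;Chlorophyta	yes
Vc	Volvox carteri	Viridiplantae;Chlorophyta	yes
Cr	Chlamydomonas reinhardtii	Viridiplantae;Chlorophyta	yes
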