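photoautotrophy	Cyanobacteria
photoautotrophy	Synechococcus
chemoheterotrophy	Actinobacteria
chemoheterotrophy	Bacteroidetes
chemoheterotrophy	Flavobacterium
methanotrophy	Methylobacter
methanotrophy	Methylococcaceae
methylotrophy	Methylobacter
methylotrophy	Methylotenera
fermentation	Clostridium
fermentation	Firmicutes
nitrogen_fixation	Nostoc
nitrogen_fixation	Azotobacter
denitrification	Pseudomonas
denitrification	Paracoccus
nitrogen_respiration	Nitrosomonas
nitrogen_respiration	Nitrospira
aerobic_ammonia_oxidation	Nitrosomonas
cellulolysis	Cellulomonas
phototrophy	Cyanobacteria
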