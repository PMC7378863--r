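genus	category	class
Sphingomonas	N fixation	nutrient_cycling
Microvirga	N fixation	nutrient_cycling
Bradyrhizobium	N fixation	nutrient_cycling
Anabaena	N fixation	nutrient_cycling
Ensifer	N fixation	nutrient_cycling
Bacillus	denitrification	nutrient_cycling
Streptomyces	denitrification	nutrient_cycling
Euzebya	denitrification	nutrient_cycling
Bosea	denitrification	nutrient_cycling
Gaiellaceae_unclassified	P solubilization	nutrient_cycling
Microlunatus	P solubilization	nutrient_cycling
Microvirga	nitrate reduction	nutrient_cycling
Craurococcus	nitrate reduction	nutrient_cycling
Bacillus	spore formation	stress_tolerance
Streptomyces	spore formation	stress_tolerance
Rubrobacter	desiccation tolerance	stress_tolerance
Euzebya	salt tolerance	stress_tolerance
Thermoleophilum	thermotolerance	stress_tolerance
Kallotenue	thermotolerance	stress_tolerance
Kallotenue	filamentous growth	environmental_adaptation
Ardenticatena	filamentous growth	environmental_adaptation
Streptomyces	antibiotic production	environmental_adaptation
Sphingomonas	EPS production	environmental_adaptation
Microlunatus	nutrient storage	environmental_adaptation
Gemmatimonas	nutrient storage	environmental_adaptation
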