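descriptor	top_level
Genomics	Biological Science Disciplines
Computational Biology	Biological Science Disciplines
Proteomics	Biological Science Disciplines
Biological Science Disciplines	Biological Science Disciplines
Neoplasms	Diseases
Cardiovascular Diseases	Diseases
Diseases	Diseases
Machine Learning	Information Science
Data Mining	Information Science
Information Science	Information Science
Software	Information Science
Humans	Organisms
Mice	Organisms
Organisms	Organisms
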