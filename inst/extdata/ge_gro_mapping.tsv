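genia	gro
Acetylation	Acetylation
Binding	BindingToProtein
Gene_expression	GeneExpression
Localization	Localization
Negative_regulation	NegativeRegulation
Phosphorylation	Phosphorylation
Positive_regulation	PositiveRegulation
Protein	Gene
Protein	Protein
Protein_catabolism	ProteinCatabolism
Protein_modification	ProteinModification
Regulation	RegulatoryProcess
Transcription	Transcription
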