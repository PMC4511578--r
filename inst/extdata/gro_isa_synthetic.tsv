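child	parent
PhysicalContinuant	Continuant
LivingEntity	PhysicalContinuant
Organism	LivingEntity
Eukaryote	Organism
Cell	LivingEntity
Tissue	PhysicalContinuant
MolecularEntity	PhysicalContinuant
InformationBiopolymer	MolecularEntity
NucleicAcid	InformationBiopolymer
DNA	NucleicAcid
Gene	NucleicAcid
ProteinDomain	InformationBiopolymer
Protein	InformationBiopolymer
TranscriptionRegulator	Protein
TranscriptionFactor	TranscriptionRegulator
Enzyme	Protein
ProteinSubunit	Protein
Chemical	MolecularEntity
OrganicChemical	Chemical
AminoAcid	OrganicChemical
CellComponent	PhysicalContinuant
Process	Occurrent
Increase	Process
Disease	Process
Mutation	Process
CellGrowth	Process
PhysicalInteraction	Process
Binding	PhysicalInteraction
BindingOfProteinToDNA	Binding
BindingOfTranscriptionFactorToDNA	BindingOfProteinToDNA
BindingToProtein	Binding
Heterodimerization	Binding
MolecularProcess	Process
Pathway	MolecularProcess
SignalingPathway	Pathway
GeneExpression	MolecularProcess
Transcription	GeneExpression
TranscriptionOfGene	Transcription
Localization	MolecularProcess
Transport	Localization
ProteinTransport	Localization
ProteinTargeting	ProteinTransport
ProteinModification	MolecularProcess
Acetylation	ProteinModification
Phosphorylation	ProteinModification
ProteinCatabolism	MolecularProcess
RegulatoryProcess	MolecularProcess
RegulationOfGeneExpression	RegulatoryProcess
PositiveRegulationOfGeneExpression	RegulationOfGeneExpression
RegulationOfTranscription	RegulatoryProcess
NegativeRegulationOfTranscription	RegulationOfTranscription
PositiveRegulationOfTranscription	RegulationOfTranscription
PositiveRegulation	RegulatoryProcess
NegativeRegulation	RegulatoryProcess
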