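target
targets
gene
genes
protein
proteins
receptor
receptors
enzyme
enzymes
kinase
kinases
expression
expressed
mutation
mutant
domain
subunit
pathway
transcription
factor
antibody
peptide
peptides
binding
encoding
regulator
phosphorylation
homolog
isoform
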