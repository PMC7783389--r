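inhibit
inhibits
inhibited
inhibition
inhibitor
inhibitors
chemical
chemicals
compound
compounds
drug
drugs
agent
agents
molecule
molecules
analog
analogs
derivative
derivatives
dose
doses
concentration
acid
salt
ligand
ligands
substrate
treatment
therapy
target
binding
potency
antagonist
agonist
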