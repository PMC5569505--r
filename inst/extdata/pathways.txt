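# Starter pathway definitions. One block per pathway; blank line between
# blocks. `components:` lists the enzyme steps, `keys:` the diagnostic
# enzymes that must be confirmed in multiple databases.

pathway: reverse_methanogenesis
name: Methanogenesis / reverse methanogenesis
components: mcrA mcrB mcrG mtrA mer mtd mch ftr fwdA
keys: mcrA

pathway: sulfate_reduction
name: Dissimilatory sulfate reduction
components: sat aprA aprB dsrA dsrB dsrC
keys: dsrA dsrB

pathway: beta_oxidation
name: Lipid beta-oxidation
components: acd ech hbd atoB
keys: acd ech hbd atoB

pathway: denitrification
name: Denitrification
components: napA narG nirS nirK norB nosZ
keys: napA

pathway: fumarate_addition
name: Fumarate-addition hydrocarbon activation
components: bssA bssB bssC assA
keys: bssA assA
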