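# Small example simulation configuration (see ?simConfig for fields)
seed: 1
nGenes: 1000
markerGenesPerType: 110
nCellsByType:
  Oligodendrocyte: 120
  Astrocyte: 50
  Microglia: 50
  Dopamine: 60
  GABAergic: 90
  VGLUT2: 90
doubletFraction: 0.05
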