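# Process-description form of the tau phosphorylation switch: the inactive
# tau species is consumed by a state transition catalyzed by the kinase
# complex and inhibited by the isomerase.
species
  id: MAPT
  active: false
species
  id: MAPTP
species
  id: CDK5_p25
species
  id: PIN1
reaction
  id: phosphorylation
  type: state_transition
  reactants: MAPT
  products: MAPTP
  modifiers: CDK5_p25:positive, PIN1:negative
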