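# Roster of the cortico-subcortical tractography protocols: the
# amygdalofugal pathway, anterior commissure, three extreme capsule parts,
# fornix, Muratoff bundle, four striatal bundle parts and the uncinate
# fasciculus. All are bilateral except the anterior commissure, which is
# commissural, so expansion yields 23 tract instances.
space: phantom
protocols:
  - {name: AMF,   laterality: bilateral}    # amygdalofugal tract
  - {name: AC,    laterality: commissural}  # anterior commissure
  - {name: EmC_f, laterality: bilateral}    # extreme capsule, frontal
  - {name: EmC_t, laterality: bilateral}    # extreme capsule, temporal
  - {name: EmC_p, laterality: bilateral}    # extreme capsule, parietal
  - {name: FX,    laterality: bilateral}    # fornix
  - {name: MB,    laterality: bilateral}    # Muratoff bundle / subcallosal fasciculus
  - {name: StB_m, laterality: bilateral}    # striatal bundle, sensorimotor
  - {name: StB_f, laterality: bilateral}    # striatal bundle, frontal
  - {name: StB_t, laterality: bilateral}    # striatal bundle, temporal
  - {name: StB_p, laterality: bilateral}    # striatal bundle, parietal
  - {name: UF,    laterality: bilateral}    # uncinate fasciculus
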