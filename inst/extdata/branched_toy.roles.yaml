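# Role designation sidecar for branched_toy.sbml: SBML carries no
# uptake/biomass/target semantics, so these are declared explicitly.
substrate_uptake: R_up
biomass_reaction: v_bio
target_reaction: v8
precursors: []
non_deletable:
  - R_up
  - v_bio
  - v8
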