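# Reference person in the engine room of a bulk carrier transporting nodules.
# Dust and radon are excluded: no air exchange with the cargo hold is assumed.
label: transport
gamma:
  - label: nodules in cargo hold
    material: nodules_bulk
    geometry: extended_surface
    distance: surface
    t_exp: 2000        # h/a, full working year
    shielding: 0.5     # transmitted fraction through ~2 cm steel + installations
    f_con: 0.6
dust: []
radon: ~
surface_multiplier: 1
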