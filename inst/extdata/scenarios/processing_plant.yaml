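# Reference person covering all workplaces of a pyrometallurgical processing
# plant: outside storage (gamma), plant interior (dust), filter maintenance.
# Radon is assessed separately at the indoor reference concentration.
label: processing_plant
gamma:
  - label: stored nodules
    material: nodules_bulk
    geometry: cone_pile     # large stockpiles: 0.4 uSv/h per Bq/g at surface
    distance: surface
    t_exp: 400
    shielding: 1
    f_con: 0.6
  - label: stored slag
    material: slag_3rd_reduction
    geometry: big_bag       # handled quantities up to 1 m^3: 0.07 at 1 m
    distance: 1m
    t_exp: 400
    shielding: 1
    f_con: 0.6
dust:
  - label: dust from nodules
    material: nodules_bulk
    c_dust: 1.25            # mg/m^3, MAC for alveolar dust, routine areas
    t_exp: 1000
    f_inh: 0
  - label: dust from slag
    material: slag_3rd_reduction
    c_dust: 1.25
    t_exp: 1000
    f_inh: 0
  - label: filter maintenance
    material: filter_dust
    c_dust: 3               # mg/m^3, occasional-exposure shift limit
    t_exp: 24               # 2 h per month
    f_inh: 0
radon:
  c_rn: 300                 # Bq/m^3, indoor workplace reference value
  t_exp: 2000
  equilibrium_factor: 0.4
surface_multiplier: 1
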