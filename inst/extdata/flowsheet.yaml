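# Pyrometallurgical flowsheet: 3 Mt/a nodule feed, three smelting stages.
# All long-lived nuclides are conservatively concentrated in the slag of the
# third reduction stage; Pb-210 and Po-210 volatilise at 1450 C and report to
# the flue dust of the first reduction stage (double-counted in the slag).
input_mass_rate_t_a: 3.0e6
stages:
  - label: slag of the 3rd reduction stage
    output_mass_rate_t_a: 1.374e6
    role: slag
  - label: filter dust of the 1st reduction stage
    output_mass_rate_t_a: 0.297e6
    role: dust
volatile_nuclides: [Pb-210, Po-210]
double_count_volatiles_in_slag: true
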