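# Design and operational data of the studied full-scale AGS plant.
# Masses in kg TSS, fluxes in kg TSS per day.
M_AGS: 55972
J_ES: 2177
J_EF: 1256
J_WW: 4122.5
mlss_fractions: {FL: 0.25, SG: 0.53, LG: 0.22}
es_fractions: {FL: 0.50, SG: 0.45, LG: 0.05}
ef_fractions: {FL: 1.0, SG: 0.0, LG: 0.0}
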