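"target_path","low","high"
"MC.rates.hematoma",0.03556,0.06604
"MC.rates.rph",0.02037,0.03783
"MC.rates.avf",0.0014,0.0026
"MC.rates.psa",0.01113,0.02067
"MC.rates.limb_ischemia",0,0
"MC.rates.infection",0.00154,0.00286
"MC.treatments.hematoma.transfusion_pta",0.0021,0.0039
"MC.treatments.rph.transfusion_pta",0.007,0.013
"MC.treatments.rph.endovascular_surgery",0.007,0.013
"MC.treatments.avf.us_guided",0.7,1
"MC.treatments.psa.us_guided",0.7,1
"MC.treatments.limb_ischemia.transfusion_pta",0.7,1
"MC.treatments.infection.antibiotics",0.7,1
"VCD.rates.hematoma",0.03192,0.05928
"VCD.rates.rph",0.02653,0.04927
"VCD.rates.avf",0.00581,0.01079
"VCD.rates.psa",0.0112,0.0208
"VCD.rates.limb_ischemia",0.00217,0.00403
"VCD.rates.infection",0.00427,0.00793
"VCD.treatments.hematoma.transfusion_pta",0.0014,0.0026
"VCD.treatments.rph.transfusion_pta",0.007,0.013
"VCD.treatments.rph.endovascular_surgery",0.007,0.013
"VCD.treatments.avf.us_guided",0.7,1
"VCD.treatments.psa.us_guided",0.7,1
"VCD.treatments.limb_ischemia.transfusion_pta",0.7,1
"VCD.treatments.infection.antibiotics",0.7,1
"VCD.failure_prob",0.0252,0.0468
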