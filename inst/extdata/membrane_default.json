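{
  "version": "1.0",
  "comment": "Cortical pyramidal membrane defaults. Densities in pS/um2, cm in uF/cm2, g_pas in S/cm2, potentials mV, Ra ohm*cm. Kinetics are the standard published cortical pyramidal channel family referenced to 23 C with q10 scaling.",
  "global": {
    "ra_ohm_cm": 150,
    "celsius": 37,
    "q10": 2.3,
    "temp_base": 23,
    "v_init": -70,
    "ena": 60,
    "ek": -90,
    "eca": 140,
    "balance_at_init": true
  },
  "sections": {
    "soma": {
      "cm": 0.75,
      "g_pas": 3.333e-05,
      "e_pas": -70,
      "gna": 20,
      "gkv": 200,
      "gkm": 0.1,
      "gca": 0.3,
      "gkca": 3
    },
    "apical": {
      "cm": 0.75,
      "g_pas": 3.333e-05,
      "e_pas": -70,
      "gna": 20,
      "gkv": 0,
      "gkm": 0.1,
      "gca": 0.3,
      "gkca": 3
    },
    "basal": {
      "cm": 0.75,
      "g_pas": 3.333e-05,
      "e_pas": -70,
      "gna": 20,
      "gkv": 0,
      "gkm": 0.1,
      "gca": 0.3,
      "gkca": 3
    },
    "ais": {
      "cm": 0.75,
      "g_pas": 3.333e-05,
      "e_pas": -70,
      "gna": 30000,
      "gkv": 2000,
      "gkm": 0,
      "gca": 0,
      "gkca": 0
    },
    "node": {
      "cm": 0.75,
      "g_pas": 3.333e-05,
      "e_pas": -70,
      "gna": 30000,
      "gkv": 2000,
      "gkm": 0,
      "gca": 0,
      "gkca": 0
    },
    "internode": {
      "cm": 0.04,
      "g_pas": 3.333e-05,
      "e_pas": -70,
      "gna": 0,
      "gkv": 0,
      "gkm": 0,
      "gca": 0,
      "gkca": 0
    },
    "axon": {
      "cm": 0.75,
      "g_pas": 3.333e-05,
      "e_pas": -70,
      "gna": 30000,
      "gkv": 2000,
      "gkm": 0,
      "gca": 0,
      "gkca": 0
    },
    "terminal": {
      "cm": 0.75,
      "g_pas": 3.333e-05,
      "e_pas": -70,
      "gna": 1000,
      "gkv": 100,
      "gkm": 0,
      "gca": 0,
      "gkca": 0
    }
  }
}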