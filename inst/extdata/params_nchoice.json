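{
  "comment": "Tuned stand-in defaults for the n-choice CBGT network build. Values chosen so all nuclei show stable, distinguishable baseline firing and decisions complete within a few hundred ms; they are not a published parameter set.",
  "celldefaults": {
    "C": 0.5,
    "Taum": 20,
    "Vrest": -70,
    "Vthresh": -50,
    "Vreset": -55,
    "refractory": 2,
    "VE": 0,
    "VI": -70
  },
  "popspecific": {
    "CxI": {
      "Taum": 10,
      "C": 0.2
    },
    "FSI": {
      "Taum": 10,
      "C": 0.2
    }
  },
  "receptordefaults": {
    "Tau_AMPA": 2,
    "Tau_GABA": 5,
    "Tau_NMDA": 100
  },
  "basestim": {
    "Cx": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0183253851003214,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "CxI": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0144773268861687,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "dSPN": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0164305463965995,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "iSPN": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0164305463965995,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "FSI": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0145260009659366,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "GPeP": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0230276448256251,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "GPeA": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0193399191679503,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "STN": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0213132103000175,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "GPi": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0255398946202632,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    },
    "Th": {
      "FreqExt_AMPA": 0.3,
      "nconn_AMPA": 400,
      "eff_AMPA": 0.0275902715757181,
      "FreqExt_GABA": 0,
      "nconn_GABA": 0,
      "eff_GABA": 0
    }
  },
  "dpmndefaults": {
    "dpmn_tauDOP": 5,
    "dpmn_dopamine_base": 0,
    "dpmn_elig_scale": 0.3
  },
  "dSPNdefaults": {
    "dpmn_alphaw": 39.5,
    "dpmn_wmax": 0.08,
    "dpmn_w0": 0.01
  },
  "iSPNdefaults": {
    "dpmn_alphaw": -38.2,
    "dpmn_wmax": 0.06,
    "dpmn_w0": 0.01
  },
  "popsizes": {
    "Cx": 40,
    "CxI": 20,
    "dSPN": 30,
    "iSPN": 30,
    "FSI": 20,
    "GPeP": 30,
    "GPeA": 20,
    "STN": 20,
    "GPi": 30,
    "Th": 80
  },
  "stimscale": 0.28,
  "dt": 0.1,
  "pathways": [
    {
      "src": "Cx",
      "dest": "CxI",
      "receptor": "AMPA",
      "type": "common",
      "con": 1,
      "eff": 0.00075,
      "plastic": false
    },
    {
      "src": "CxI",
      "dest": "Cx",
      "receptor": "GABA",
      "type": "common",
      "con": 1,
      "eff": 0.002,
      "plastic": false
    },
    {
      "src": "CxI",
      "dest": "CxI",
      "receptor": "GABA",
      "type": "common",
      "con": 1,
      "eff": 0.0005,
      "plastic": false
    },
    {
      "src": "Cx",
      "dest": "dSPN",
      "receptor": "AMPA",
      "type": "syn",
      "con": 1,
      "eff": 0.001,
      "plastic": false
    },
    {
      "src": "Cx",
      "dest": "iSPN",
      "receptor": "AMPA",
      "type": "syn",
      "con": 1,
      "eff": 0.001,
      "plastic": false
    },
    {
      "src": "Cx",
      "dest": "dSPN",
      "receptor": "NMDA",
      "type": "syn",
      "con": 1,
      "eff": 0.01,
      "plastic": true
    },
    {
      "src": "Cx",
      "dest": "iSPN",
      "receptor": "NMDA",
      "type": "syn",
      "con": 1,
      "eff": 0.01,
      "plastic": true
    },
    {
      "src": "Cx",
      "dest": "FSI",
      "receptor": "AMPA",
      "type": "common",
      "con": 1,
      "eff": 0.0004,
      "plastic": false
    },
    {
      "src": "Cx",
      "dest": "STN",
      "receptor": "AMPA",
      "type": "syn",
      "con": 1,
      "eff": 0.00115,
      "plastic": false
    },
    {
      "src": "Cx",
      "dest": "Th",
      "receptor": "AMPA",
      "type": "syn",
      "con": 1,
      "eff": 0.00115,
      "plastic": false
    },
    {
      "src": "FSI",
      "dest": "dSPN",
      "receptor": "GABA",
      "type": "syn",
      "con": 1,
      "eff": 0.0015,
      "plastic": false
    },
    {
      "src": "FSI",
      "dest": "iSPN",
      "receptor": "GABA",
      "type": "syn",
      "con": 1,
      "eff": 0.0015,
      "plastic": false
    },
    {
      "src": "dSPN",
      "dest": "GPi",
      "receptor": "GABA",
      "type": "syn",
      "con": 1,
      "eff": 0.002,
      "plastic": false
    },
    {
      "src": "iSPN",
      "dest": "GPeP",
      "receptor": "GABA",
      "type": "syn",
      "con": 1,
      "eff": 0.0025,
      "plastic": false
    },
    {
      "src": "GPeP",
      "dest": "STN",
      "receptor": "GABA",
      "type": "syn",
      "con": 1,
      "eff": 0.0005,
      "plastic": false
    },
    {
      "src": "GPeP",
      "dest": "GPi",
      "receptor": "GABA",
      "type": "syn",
      "con": 1,
      "eff": 0.0005,
      "plastic": false
    },
    {
      "src": "STN",
      "dest": "GPeP",
      "receptor": "AMPA",
      "type": "syn",
      "con": 1,
      "eff": 0.0005,
      "plastic": false
    },
    {
      "src": "STN",
      "dest": "GPi",
      "receptor": "AMPA",
      "type": "common",
      "con": 1,
      "eff": 0.0015,
      "plastic": false
    },
    {
      "src": "GPi",
      "dest": "Th",
      "receptor": "GABA",
      "type": "syn",
      "con": 1,
      "eff": 0.0025,
      "plastic": false
    },
    {
      "src": "Th",
      "dest": "Cx",
      "receptor": "AMPA",
      "type": "syn",
      "con": 1,
      "eff": 0.0001,
      "plastic": false
    },
    {
      "src": "Th",
      "dest": "dSPN",
      "receptor": "AMPA",
      "type": "syn",
      "con": 1,
      "eff": 5e-05,
      "plastic": false
    },
    {
      "src": "Th",
      "dest": "iSPN",
      "receptor": "AMPA",
      "type": "syn",
      "con": 1,
      "eff": 5e-05,
      "plastic": false
    },
    {
      "src": "Cx",
      "dest": "dSPN",
      "receptor": "NMDA",
      "type": "syn",
      "con": 1,
      "eff": 0.0001,
      "plastic": false
    },
    {
      "src": "Cx",
      "dest": "iSPN",
      "receptor": "NMDA",
      "type": "syn",
      "con": 1,
      "eff": 0.0001,
      "plastic": false
    }
  ],
  "bg_jitter": 0,
  "plastic_gain": 0.015
}
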