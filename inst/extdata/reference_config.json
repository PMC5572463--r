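{
  "name": "lateral-wall reference model",
  "description": "Closed-loop six-membrane model of the cochlear lateral wall, calibrated so the stored potentials/concentrations are an exact steady state carrying a 3 nA circulation current.",
  "provenance": [
    "Element magnitudes are steady-state calibrated fallbacks; see each element's note.",
    "Volumes: equal ~2 pL cell volumes from slice morphometry; perilymph/endolymph as whole-cochlea quasi-infinite baths.",
    "Capacitances: 10 pF per cell per membrane domain.",
    "Pump kinetics: Michaelis-Menten in extracellular K+ (Km 1.5 mM, Hill 2); Na+-saturated (Hill 0)."
  ],
  "constants": {
    "T": 310.15
  },
  "compartments": [
    {
      "id": "perilymph_ST",
      "volume_l": 8.9e-06,
      "dynamic": true,
      "conc": {
        "K": 5,
        "Na": 145,
        "Cl": 130
      }
    },
    {
      "id": "syncytium",
      "volume_l": 4.11918133714286e-10,
      "dynamic": true,
      "conc": {
        "K": 98.3,
        "Na": 10,
        "Cl": 35
      }
    },
    {
      "id": "intrastrial_space",
      "volume_l": 1.5e-14,
      "dynamic": true,
      "conc": {
        "K": 6.1,
        "Na": 145,
        "Cl": 130
      }
    },
    {
      "id": "marginal_cell",
      "volume_l": 3.16860102857143e-11,
      "dynamic": true,
      "conc": {
        "K": 140,
        "Na": 10,
        "Cl": 35
      }
    },
    {
      "id": "hair_cell",
      "volume_l": 5.94112692857143e-12,
      "dynamic": true,
      "conc": {
        "K": 140,
        "Na": 10,
        "Cl": 35
      }
    },
    {
      "id": "endolymph",
      "volume_l": 2e-06,
      "dynamic": true,
      "conc": {
        "K": 150,
        "Na": 1,
        "Cl": 130
      }
    }
  ],
  "membranes": [
    {
      "id": "SB",
      "inner": "syncytium",
      "outer": "perilymph_ST",
      "capacitance_nf": 1.68,
      "potential_mv": 9.6,
      "elements": [
        {
          "kind": "nak_atpase",
          "magnitude": 0.0187820981982553,
          "n_cells": 168,
          "label": "nak_atpase",
          "provenance": "fallback: SB pump activity from the basolateral balance system (steady-state calibration; primary source unavailable)",
          "params": {
            "km_na_mM": 10,
            "km_k_mM": 1.5,
            "hill_na": 0,
            "hill_k": 2
          }
        },
        {
          "kind": "ohmic_channel",
          "magnitude": 0.489889825387786,
          "n_cells": 168,
          "label": "na_conductance",
          "provenance": "fallback: SB Na+ conductance, ratio closure g_Na = 5 g_leak (steady-state calibration; primary source unavailable)",
          "ions": {
            "Na": 1
          }
        },
        {
          "kind": "leak_conductance",
          "magnitude": 0.0979779650775571,
          "n_cells": 168,
          "label": "leak",
          "provenance": "fallback: SB leak, equal K+/Na+ partial conductances (steady-state calibration; primary source unavailable)",
          "ions": {
            "K": 0.5,
            "Na": 0.5
          }
        }
      ]
    },
    {
      "id": "SA",
      "inner": "syncytium",
      "outer": "intrastrial_space",
      "capacitance_nf": 0.4,
      "potential_mv": -71.6,
      "elements": [
        {
          "kind": "ohmic_channel",
          "magnitude": 27.8496028244501,
          "n_cells": 40,
          "label": "kir_k_channel",
          "provenance": "fallback: apical syncytial K+ conductance carrying I_cir (steady-state calibration; primary source unavailable)",
          "ions": {
            "K": 1
          }
        }
      ]
    },
    {
      "id": "MB",
      "inner": "marginal_cell",
      "outer": "intrastrial_space",
      "capacitance_nf": 0.16,
      "potential_mv": 1.5,
      "elements": [
        {
          "kind": "nak_atpase",
          "magnitude": 0.145525396398818,
          "n_cells": 16,
          "label": "nak_atpase",
          "provenance": "fallback: MB pump activity, K+ uptake = I_cir/2 per cycle stoichiometry (steady-state calibration; primary source unavailable)",
          "params": {
            "km_na_mM": 10,
            "km_k_mM": 1.5,
            "hill_na": 0,
            "hill_k": 2
          }
        },
        {
          "kind": "ohmic_channel",
          "magnitude": 4.0195189629796,
          "n_cells": 16,
          "label": "na_conductance",
          "provenance": "fallback: MB Na+ conductance returning pumped Na+ from the intrastrial space (steady-state calibration; primary source unavailable)",
          "ions": {
            "Na": 1
          }
        }
      ]
    },
    {
      "id": "MA",
      "inner": "marginal_cell",
      "outer": "endolymph",
      "capacitance_nf": 0.16,
      "potential_mv": 10,
      "elements": [
        {
          "kind": "ohmic_channel",
          "magnitude": 22.9890665252051,
          "n_cells": 16,
          "label": "kcnq_k_channel",
          "provenance": "fallback: marginal apical K+ conductance carrying I_cir (steady-state calibration; primary source unavailable)",
          "ions": {
            "K": 1
          }
        }
      ]
    },
    {
      "id": "HB",
      "inner": "hair_cell",
      "outer": "perilymph_ST",
      "capacitance_nf": 0.03,
      "potential_mv": -50,
      "elements": [
        {
          "kind": "ohmic_channel",
          "magnitude": 25.6024945182083,
          "n_cells": 3,
          "label": "k_channel",
          "provenance": "fallback: hair-cell basolateral K+ conductance carrying I_cir (steady-state calibration; primary source unavailable)",
          "ions": {
            "K": 1
          }
        }
      ]
    },
    {
      "id": "HA",
      "inner": "hair_cell",
      "outer": "endolymph",
      "capacitance_nf": 0.03,
      "potential_mv": -122.7,
      "elements": [
        {
          "kind": "met_channel",
          "magnitude": 8.02929414372106,
          "n_cells": 3,
          "label": "met_channel",
          "provenance": "resting MET current ~1 nA per hair cell"
        }
      ]
    }
  ],
  "scenario": {
    "t_settle_s": 600,
    "t_block_s": 2400,
    "kappa": 0.46,
    "dt_out_s": 1
  }
}
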