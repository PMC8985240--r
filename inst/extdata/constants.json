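{
  "version": "1.0",
  "esol": {
    "comment": "Delaney ESOL linear model: logS = intercept + c_logp*WLOGP + c_mw*MW + c_rb*rotatable_bonds + c_ap*aromatic_proportion",
    "intercept": 0.16,
    "c_logp": -0.63,
    "c_mw": -0.0062,
    "c_rb": 0.066,
    "c_ap": -0.74
  },
  "rules": {
    "lipinski": {
      "mw_max": 500, "wlogp_max": 5, "hbd_max": 5, "hba_max": 10,
      "allowed_violations": 1
    },
    "ghose": {
      "mw_min": 160, "mw_max": 480, "wlogp_min": -0.4, "wlogp_max": 5.6,
      "mr_min": 40, "mr_max": 130, "atoms_min": 20, "atoms_max": 70,
      "allowed_violations": 0
    },
    "veber": {
      "rotatable_max": 10, "tpsa_max": 140,
      "allowed_violations": 0
    },
    "egan": {
      "wlogp_max": 5.88, "tpsa_max": 131.6,
      "allowed_violations": 0
    },
    "muegge": {
      "mw_min": 200, "mw_max": 600, "wlogp_min": -2, "wlogp_max": 5,
      "tpsa_max": 150, "rings_max": 7, "carbons_min": 5, "heteroatoms_min": 2,
      "rotatable_max": 15, "hba_max": 10, "hbd_max": 5,
      "allowed_violations": 0
    },
    "leadlikeness": {
      "mw_min": 250, "mw_max": 350, "wlogp_max": 3.5, "rotatable_max": 7,
      "allowed_violations": 0
    }
  },
  "bioavailability": {
    "comment": "Abbott bioavailability score (Martin 2005): anions are scored on TPSA, everything else on the rule-of-five",
    "anion_tpsa_high": 150, "anion_tpsa_low": 75,
    "score_anion_high_tpsa": 0.11, "score_anion_mid_tpsa": 0.56,
    "score_anion_low_tpsa": 0.85,
    "score_ro5_pass": 0.55, "score_ro5_fail": 0.17
  },
  "boiled_egg": {
    "comment": "Best-fit ellipses of the BOILED-Egg model in (TPSA [A^2], WLOGP) space; white = high gastrointestinal absorption, yolk = BBB permeation. Angles in degrees.",
    "white": {"cx": 71.051, "cy": 2.292, "rx": 71.040, "ry": 4.370, "angle_deg": -1.031325},
    "yolk": {"cx": 38.117, "cy": 3.481, "rx": 41.031, "ry": 5.557, "angle_deg": -0.14882}
  },
  "printed_reference_pairs": {
    "comment": "Published MCS-Tanimoto coefficients used to calibrate the match semantics",
    "pairs": [
      {"a": "HPMA", "b": "HEMA", "tanimoto": 0.92},
      {"a": "AA", "b": "DMA", "tanimoto": 0.78},
      {"a": "CBMA", "b": "VPPS", "tanimoto": 0.21},
      {"a": "SBMA", "b": "CBMA", "tanimoto": 0.73}
    ]
  }
}
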