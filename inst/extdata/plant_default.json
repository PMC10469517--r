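{
  "comment": "Default soil-plant network for a potted pyrethrum plant. Printed values: organ K_max/alpha/g_res/vulnerability (measured parameter table), soil volume 0.054 m3 per 0.67 m2 combined evaporating area, root length 68.6 m, loam retention. All other entries are declared supplementary defaults and may be overridden.",
  "areas": { "leaf": 0.6, "flower": 0.07 },
  "organs": {
    "root":   { "k_abs": 5.0,  "v_sym_ml": 49, "v_apo_ml": 6.0, "k_sym_abs": 2.0,
                "pi0": -1.2, "epsilon": 10, "a": 1.53, "p50": -6.48 },
    "stem":   { "k_abs": 8.0,  "v_sym_ml": 35, "v_apo_ml": 5.0, "k_sym_abs": 2.0,
                "pi0": -1.2, "epsilon": 10, "a": 1.53, "p50": -6.48 },
    "branch": { "k_abs": 6.0,  "v_sym_ml": 21, "v_apo_ml": 3.0, "k_sym_abs": 2.0,
                "pi0": -1.2, "epsilon": 10, "a": 1.53, "p50": -6.48 },
    "leaf":   { "k_max_area": 8.57, "g_res": [4.68, 5.01],
                "v_sym_ml": 56, "v_apo_ml": 6.0, "k_sym_abs": 3.0,
                "pi0": -1.2, "epsilon": 10, "a": 1.53, "p50": -6.48 },
    "flower": { "k_max_area": 2.60, "g_res": [12.15, 13.98],
                "v_sym_ml": 6, "v_apo_ml": 1.0, "k_sym_abs": 0.4,
                "pi0": -1.2, "epsilon": 10, "a": 4.89, "p50": -3.57 }
  },
  "reference_temperature": 20,
  "soil": {
    "volume_m3": 0.054,
    "theta_r": 0.078, "theta_s": 0.43, "alpha_MPa_inv": 367, "n": 1.56,
    "root_length_m": 68.6,
    "k_rhizosphere_max": 3e8
  },
  "stomata": {
    "g_s_max": 150, "psi_gs50": -1.6, "k_gs": 4.39, "light_half_ppfd": 150
  },
  "energy_budget": {
    "absorptance": 0.5, "k_rad_W_per_umol": 0.22, "g_bH_W_m2_K": 25,
    "lambda_J_per_mmol": 44.2
  }
}
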