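{
  "schema": "patchyllps-parameters/1",
  "type": "buffer_fixtures",
  "comment": "0.1 M buffers at pH 7.0 for HEWL. eps0 (K) and salt_coeff a (K L^1/2 mol^-1/2) are the fitted square-well parameters; metadata carries the measured kD (mL/g), B22 (mol mL/g^2), Jones-Dole B (L/mol at 5 and 25 C) and their printed uncertainties.",
  "buffers": [
    {
      "name": "phosphate",
      "eps0": 2250, "eps0_sd": 10,
      "salt_coeff": 500, "salt_coeff_sd": 20,
      "metadata": {
        "kD_mL_g": -7.1, "kD_sd": 0.8,
        "B22_mol_mL_g2": -1.2e-4, "B22_sd": 0.2e-4,
        "jones_dole_B_5C": 0.47, "jones_dole_B_5C_sd": 0.04,
        "jones_dole_B_25C": 0.50, "jones_dole_B_25C_sd": 0.02,
        "eps0_sd": 10, "salt_coeff_sd": 20
      }
    },
    {
      "name": "HEPES",
      "eps0": 2140, "eps0_sd": 10,
      "salt_coeff": 630, "salt_coeff_sd": 40,
      "metadata": {
        "kD_mL_g": 13.5, "kD_sd": 0.5,
        "B22_mol_mL_g2": 2.0e-4, "B22_sd": 2.2e-4,
        "jones_dole_B_5C": 0.66, "jones_dole_B_5C_sd": 0.06,
        "jones_dole_B_25C": 0.60, "jones_dole_B_25C_sd": 0.06,
        "eps0_sd": 10, "salt_coeff_sd": 40
      }
    },
    {
      "name": "MOPS",
      "eps0": 1990, "eps0_sd": 10,
      "salt_coeff": 890, "salt_coeff_sd": 40,
      "metadata": {
        "kD_mL_g": 11.0, "kD_sd": 2.0,
        "B22_mol_mL_g2": 5.9e-4, "B22_sd": 0.2e-4,
        "jones_dole_B_5C": 0.79, "jones_dole_B_5C_sd": 0.17,
        "jones_dole_B_25C": 0.74, "jones_dole_B_25C_sd": 0.13,
        "eps0_sd": 10, "salt_coeff_sd": 40
      }
    },
    {
      "name": "cacodylate",
      "eps0": 1940, "eps0_sd": 20,
      "salt_coeff": 1090, "salt_coeff_sd": 70,
      "metadata": {
        "kD_mL_g": 12.0, "kD_sd": 1.0,
        "B22_mol_mL_g2": 3.1e-4, "B22_sd": 0.2e-4,
        "jones_dole_B_5C": 0.84, "jones_dole_B_5C_sd": 0.15,
        "jones_dole_B_25C": 0.52, "jones_dole_B_25C_sd": 0.05,
        "eps0_sd": 20, "salt_coeff_sd": 70
      }
    }
  ]
}
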