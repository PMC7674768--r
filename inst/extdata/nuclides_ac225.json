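{
  "comment": "Ac-225 decay series to the stable Bi-209 endpoint (endpoint omitted). Emission energies are yield-weighted mean totals per decay of each nuclide (MeV/decay), transcribed (rounded) from publicly available evaluated decay data (NNDC NuDat / MIRD-style compilations, consistent with ICRP Publication 107). Branching at Bi-213 uses 98% Po-213 / 2% Tl-209; Bi-213's own alpha energy (5.875 MeV line) is stored per Bi-213 decay as 0.02 x 5.875 MeV for consistency with that branch fraction. Gamma totals include X-rays.",
  "nuclides": [
    {"name": "Ac-225", "half_life_h": 238.08,     "yield": 1.0,  "e_alpha_mev": 5.7866, "e_beta_mev": 0.0218, "e_gamma_mev": 0.0179},
    {"name": "Fr-221", "half_life_h": 0.08002,    "yield": 1.0,  "e_alpha_mev": 6.3020, "e_beta_mev": 0.0102, "e_gamma_mev": 0.0310},
    {"name": "At-217", "half_life_h": 9.056e-06,  "yield": 1.0,  "e_alpha_mev": 7.0669, "e_beta_mev": 0.0001, "e_gamma_mev": 0.0002},
    {"name": "Bi-213", "half_life_h": 0.76017,    "yield": 1.0,  "e_alpha_mev": 0.1175, "e_beta_mev": 0.4250, "e_gamma_mev": 0.1320},
    {"name": "Po-213", "half_life_h": 1.1722e-09, "yield": 0.98, "e_alpha_mev": 8.3760, "e_beta_mev": 0.0,    "e_gamma_mev": 0.0},
    {"name": "Tl-209", "half_life_h": 0.03602,    "yield": 0.02, "e_alpha_mev": 0.0,    "e_beta_mev": 0.6590, "e_gamma_mev": 2.1800},
    {"name": "Pb-209", "half_life_h": 3.253,      "yield": 1.0,  "e_alpha_mev": 0.0,    "e_beta_mev": 0.1978, "e_gamma_mev": 0.0}
  ]
}
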