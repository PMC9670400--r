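{
  "description": "Published mean +/- SEM gating parameters of human Cav3.2 (CACNA1H) wild-type and 13 trigeminal-neuralgia-associated missense variants expressed in tsA-201 cells. Activation: Gmax (nS/pF), half-activation voltage (mV), slope factor (mV), n cells. Inactivation: half-inactivation voltage (mV), slope factor (mV, negative as conventionally reported), n cells. Recovery from inactivation: single-exponential time constant (ms), n cells. Slope factors for inactivation are re-signed positive on load (stored-positive convention).",
  "v_rev_mV": 40,
  "variants": [
    {"label": "WT",     "gmax": 0.84, "gmax_sem": 0.07, "vh_act": -38.17, "vh_act_sem": 0.80, "k_act": 6.38, "k_act_sem": 0.35, "n_act": 38, "vh_inact": -61.61, "vh_inact_sem": 1.75, "k_inact": -4.48, "k_inact_sem": 0.22, "n_inact": 19, "tau_rec": 644, "tau_rec_sem": 49,  "n_rec": 15},
    {"label": "P30L",   "gmax": 0.77, "gmax_sem": 0.11, "vh_act": -44.18, "vh_act_sem": 1.24, "k_act": 4.70, "k_act_sem": 0.51, "n_act": 15, "vh_inact": -65.95, "vh_inact_sem": 2.67, "k_inact": -4.75, "k_inact_sem": 0.44, "n_inact": 7,  "tau_rec": 705, "tau_rec_sem": 200, "n_rec": 5},
    {"label": "S187L",  "gmax": 1.01, "gmax_sem": 0.15, "vh_act": -51.63, "vh_act_sem": 2.56, "k_act": 3.47, "k_act_sem": 0.50, "n_act": 17, "vh_inact": -70.21, "vh_inact_sem": 3.99, "k_inact": -4.10, "k_inact_sem": 0.34, "n_inact": 7,  "tau_rec": 400, "tau_rec_sem": 39,  "n_rec": 6},
    {"label": "I799V",  "gmax": 0.65, "gmax_sem": 0.10, "vh_act": -41.78, "vh_act_sem": 1.58, "k_act": 5.62, "k_act_sem": 0.69, "n_act": 19, "vh_inact": -64.22, "vh_inact_sem": 1.71, "k_inact": -4.27, "k_inact_sem": 0.51, "n_inact": 10, "tau_rec": 382, "tau_rec_sem": 76,  "n_rec": 8},
    {"label": "A802V",  "gmax": 0.85, "gmax_sem": 0.09, "vh_act": -48.82, "vh_act_sem": 1.14, "k_act": 3.56, "k_act_sem": 0.45, "n_act": 14, "vh_inact": -70.79, "vh_inact_sem": 3.80, "k_inact": -4.16, "k_inact_sem": 0.39, "n_inact": 6,  "tau_rec": 241, "tau_rec_sem": 28,  "n_rec": 10},
    {"label": "E819K",  "gmax": 0.66, "gmax_sem": 0.12, "vh_act": -48.19, "vh_act_sem": 2.97, "k_act": 4.31, "k_act_sem": 0.53, "n_act": 14, "vh_inact": -65.31, "vh_inact_sem": 2.86, "k_inact": -5.18, "k_inact_sem": 0.55, "n_inact": 9,  "tau_rec": 335, "tau_rec_sem": 38,  "n_rec": 5},
    {"label": "Q1049H", "gmax": 0.70, "gmax_sem": 0.11, "vh_act": -41.88, "vh_act_sem": 2.42, "k_act": 4.99, "k_act_sem": 0.67, "n_act": 14, "vh_inact": -65.68, "vh_inact_sem": 1.74, "k_inact": -4.44, "k_inact_sem": 0.28, "n_inact": 7,  "tau_rec": 185, "tau_rec_sem": 24,  "n_rec": 5},
    {"label": "P1120L", "gmax": 0.91, "gmax_sem": 0.13, "vh_act": -49.55, "vh_act_sem": 3.17, "k_act": 4.23, "k_act_sem": 0.56, "n_act": 10, "vh_inact": -64.38, "vh_inact_sem": 3.53, "k_inact": -3.64, "k_inact_sem": 0.57, "n_inact": 7,  "tau_rec": 489, "tau_rec_sem": 197, "n_rec": 6},
    {"label": "P1605H", "gmax": 0.76, "gmax_sem": 0.06, "vh_act": -34.53, "vh_act_sem": 1.60, "k_act": 8.17, "k_act_sem": 0.34, "n_act": 15, "vh_inact": -61.32, "vh_inact_sem": 0.51, "k_inact": -5.10, "k_inact_sem": 0.19, "n_inact": 12, "tau_rec": 470, "tau_rec_sem": 46,  "n_rec": 10},
    {"label": "R1674H", "gmax": 0.37, "gmax_sem": 0.07, "vh_act": -38.23, "vh_act_sem": 2.30, "k_act": 6.49, "k_act_sem": 0.99, "n_act": 8,  "vh_inact": -63.29, "vh_inact_sem": 2.49, "k_inact": -6.05, "k_inact_sem": 1.04, "n_inact": 7,  "tau_rec": 397, "tau_rec_sem": 103, "n_rec": 6},
    {"label": "R1736C", "gmax": 0.60, "gmax_sem": 0.05, "vh_act": -32.42, "vh_act_sem": 1.38, "k_act": 7.39, "k_act_sem": 0.29, "n_act": 15, "vh_inact": -62.48, "vh_inact_sem": 0.73, "k_inact": -5.50, "k_inact_sem": 0.11, "n_inact": 12, "tau_rec": 665, "tau_rec_sem": 68,  "n_rec": 7},
    {"label": "D1779Y", "gmax": 0.72, "gmax_sem": 0.11, "vh_act": -33.86, "vh_act_sem": 1.12, "k_act": 8.08, "k_act_sem": 0.27, "n_act": 15, "vh_inact": -64.23, "vh_inact_sem": 1.07, "k_inact": -5.03, "k_inact_sem": 0.11, "n_inact": 12, "tau_rec": 662, "tau_rec_sem": 58,  "n_rec": 8},
    {"label": "P2280H", "gmax": 1.12, "gmax_sem": 0.16, "vh_act": -53.12, "vh_act_sem": 2.31, "k_act": 3.87, "k_act_sem": 0.37, "n_act": 11, "vh_inact": -74.22, "vh_inact_sem": 1.89, "k_inact": -4.56, "k_inact_sem": 0.37, "n_inact": 10, "tau_rec": 334, "tau_rec_sem": 42,  "n_rec": 7},
    {"label": "E2291K", "gmax": 0.81, "gmax_sem": 0.15, "vh_act": -46.13, "vh_act_sem": 2.01, "k_act": 4.91, "k_act_sem": 0.69, "n_act": 17, "vh_inact": -65.27, "vh_inact_sem": 1.83, "k_inact": -4.23, "k_inact_sem": 0.19, "n_inact": 11, "tau_rec": 429, "tau_rec_sem": 80,  "n_rec": 8}
  ]
}
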