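{
  "description": "Pinned parameter set of the package's three-compartment reticular-thalamic (nRT) neuron: a soma carrying fast Na+/K+ spike currents (Traub-style kinetics) and two dendritic sections, passive leak and axial coupling throughout, and low-threshold T-type Ca2+ current (constant-field flux, gate exponent 2) concentrated in the dendrites, following the reduced nRT cell of Destexhe et al. (1996) in structure and T-current kinetics (Q10 factors 5 and 3 referenced to 24 degC; simulated at 36 degC). Densities and passive properties were calibrated once so the cell rests stably at -70 mV under a solved bias current, fires sustained tonic trains during 200 ms depolarizing injections, and produces a terminating post-inhibitory rebound burst after sufficiently deep 200 ms hyperpolarizing injections.",
  "version": "1.0",
  "geometry": {
    "soma":  {"L_um": 38.42, "diam_um": 26.0},
    "dend1": {"L_um": 120.0, "diam_um": 10.0},
    "dend2": {"L_um": 150.0, "diam_um": 7.0}
  },
  "Ra_ohm_cm": 150.0,
  "cm_uF_cm2": 1.0,
  "g_pas_S_cm2": 1e-4,
  "e_pas_mV": -72.0,
  "g_na_S_cm2": 0.25,
  "g_k_S_cm2": 0.08,
  "e_na_mV": 50.0,
  "e_k_mV": -90.0,
  "vtraub_mV": -71.0,
  "pcat_cm_s": {"soma": 2e-6, "dend1": 8e-5, "dend2": 8e-5},
  "cai_mM": 2.4e-4,
  "cao_mM": 2.0,
  "celsius": 36.0,
  "t_gate_exponent": 2
}
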