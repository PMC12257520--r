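{
  "name": "q-TIP4P/F",
  "version": "1.0",
  "units": {"length": "nm", "energy": "kJ/mol", "mass": "amu", "time": "ps", "charge": "e"},
  "stretch": {
    "D_r": 485.72056,
    "alpha_r": 22.87,
    "r_eq": 0.09419,
    "comment": "quartic expansion of a Morse potential: D_r*(a^2 d^2 - a^3 d^3 + 7/12 a^4 d^4), d = r - r_eq"
  },
  "bend": {
    "k_theta": 367.5644,
    "theta_eq_deg": 107.4
  },
  "lj": {
    "epsilon": 0.7748768,
    "sigma": 0.31589
  },
  "charges": {
    "q_H": 0.5564,
    "q_M": -1.1128
  },
  "m_site_weight": 0.73612,
  "cutoff": {
    "r_c": 1.0,
    "eps_rf": 78.3,
    "shift_rf": true
  },
  "masses_amu": {
    "O": 15.9949,
    "H": 1.00783,
    "D": 2.01410,
    "T": 3.01605
  }
}
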