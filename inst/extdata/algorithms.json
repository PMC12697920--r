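{
  "version": "1.0",
  "comment": "Weighted-window sleep-wake scoring algorithm registry. Offsets are 30-second epochs relative to the scored epoch; out-of-range window positions contribute zero activity. Decision rules compare the raw score to the threshold.",
  "algorithms": {
    "cole_kripke": {
      "label": "Cole-Kripke",
      "window_offsets": [-4, -3, -2, -1, 0, 1, 2],
      "weights": [50, 30, 14, 28, 121, 8, 50],
      "scale": 0.0001,
      "threshold": 1,
      "decision": "sleep_if_score_lt_threshold"
    },
    "ucsd": {
      "label": "UCSD",
      "window_offsets": [-4, -3, -2, -1, 0, 1, 2],
      "weights": [0.010, 0.015, 0.028, 0.031, 0.085, 0.015, 0.010],
      "scale": 0.05,
      "threshold": 1,
      "decision": "sleep_if_score_lt_threshold"
    },
    "kripke2010": {
      "label": "Kripke 2010",
      "window_offsets": [-10, -9, -8, -7, -6, -5, -4, -3, -2, -1, 0, 1, 2],
      "weights": [0.0064, 0.0074, 0.0112, 0.0112, 0.0118, 0.0118, 0.0128,
                  0.0188, 0.0280, 0.0664, 0.0300, 0.0112, 0.0100],
      "scale": 0.30,
      "threshold": 1,
      "decision": "sleep_if_score_lt_threshold"
    },
    "philips": {
      "label": "Philips-Respironics",
      "window_offsets": [-4, -3, -2, -1, 0, 1, 2, 3, 4],
      "weights": [0.04, 0.04, 0.2, 0.2, 2, 0.2, 0.2, 0.04, 0.04],
      "scale": 1,
      "threshold": 40,
      "thresholds": [20, 40, 80],
      "decision": "sleep_if_score_le_threshold"
    },
    "sadeh": {
      "label": "Sadeh",
      "special": "sadeh",
      "window_before": 5,
      "window_after": 5,
      "sd_epochs": 6,
      "clip": 300,
      "log_offset": 1,
      "intercept": 7.601,
      "coef_avg": 0.065,
      "coef_nats": 1.08,
      "coef_sd": 0.056,
      "coef_lg": 0.703,
      "nats_low": 50,
      "nats_high": 100,
      "threshold": 0,
      "decision": "sleep_if_score_ge_threshold"
    }
  }
}
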