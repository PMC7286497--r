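{
  "version": "1.0",
  "reference_interval_s": 5,
  "comment": "Calibration assumptions for the seven artisanal gear archetypes. Anchored values: handline fishing events can be as short as 600 s; purse seine trips down to 2.3 h and 26 km; surface drifting gillnet trips up to 76.2 h and 165 km; fishing speed mode below the 7 km/h visual-interpretation threshold and transit mode below the 50 km/h speed filter; per-gear speed distributions bimodal. Exact speed modes, spreads, angle concentrations, transition diagonals and the remaining event-duration floors are this package's own stated calibration choices and are never used as acceptance truth.",
  "profiles": {
    "SCG": {
      "gear": "SCG",
      "label": "sardine circling gillnet",
      "fishing": {"speed_mode_kmh": 3.0, "speed_cv": 0.8, "angle_mean": 0.0, "angle_concentration": 0.7},
      "non_fishing": {"speed_mode_kmh": 14.0, "speed_cv": 0.25, "angle_mean": 0.0, "angle_concentration": 12.0},
      "A": [[0.9981481, 0.0018519], [0.0020833, 0.9979167]],
      "trip_duration_range_h": [4.0, 10.0],
      "min_fishing_event_s": 1200,
      "start_area": {"lat": [0.2, 1.0], "lon": [9.0, 9.5]},
      "heading_persistence": 12.0
    },
    "SG": {
      "gear": "SG",
      "label": "surface drifting gillnet",
      "fishing": {"speed_mode_kmh": 1.5, "speed_cv": 0.8, "angle_mean": 0.0, "angle_concentration": 0.5},
      "non_fishing": {"speed_mode_kmh": 12.0, "speed_cv": 0.25, "angle_mean": 0.0, "angle_concentration": 10.0},
      "A": [[0.9996528, 0.0003472], [0.0020833, 0.9979167]],
      "trip_duration_range_h": [24.0, 76.2],
      "min_fishing_event_s": 7200,
      "start_area": {"lat": [0.2, 1.0], "lon": [9.0, 9.5]},
      "heading_persistence": 10.0
    },
    "MCG": {
      "gear": "MCG",
      "label": "mullet circling gillnet",
      "fishing": {"speed_mode_kmh": 3.0, "speed_cv": 0.8, "angle_mean": 0.0, "angle_concentration": 0.7},
      "non_fishing": {"speed_mode_kmh": 13.0, "speed_cv": 0.25, "angle_mean": 0.0, "angle_concentration": 12.0},
      "A": [[0.9981481, 0.0018519], [0.0020833, 0.9979167]],
      "trip_duration_range_h": [4.0, 12.0],
      "min_fishing_event_s": 1200,
      "start_area": {"lat": [0.2, 1.0], "lon": [9.0, 9.5]},
      "heading_persistence": 12.0
    },
    "PS": {
      "gear": "PS",
      "label": "purse seine",
      "fishing": {"speed_mode_kmh": 4.0, "speed_cv": 0.8, "angle_mean": 0.0, "angle_concentration": 0.7},
      "non_fishing": {"speed_mode_kmh": 16.0, "speed_cv": 0.25, "angle_mean": 0.0, "angle_concentration": 12.0},
      "A": [[0.9986111, 0.0013889], [0.0027778, 0.9972222]],
      "trip_duration_range_h": [2.3, 10.0],
      "min_fishing_event_s": 1800,
      "start_area": {"lat": [0.2, 1.0], "lon": [9.0, 9.5]},
      "heading_persistence": 12.0
    },
    "HL": {
      "gear": "HL",
      "label": "handline",
      "fishing": {"speed_mode_kmh": 1.0, "speed_cv": 0.8, "angle_mean": 0.0, "angle_concentration": 0.5},
      "non_fishing": {"speed_mode_kmh": 15.0, "speed_cv": 0.25, "angle_mean": 0.0, "angle_concentration": 12.0},
      "A": [[0.9972222, 0.0027778], [0.0041667, 0.9958333]],
      "trip_duration_range_h": [10.0, 48.0],
      "min_fishing_event_s": 600,
      "start_area": {"lat": [0.2, 1.0], "lon": [9.0, 9.5]},
      "heading_persistence": 12.0
    },
    "LL": {
      "gear": "LL",
      "label": "longline",
      "fishing": {"speed_mode_kmh": 3.5, "speed_cv": 0.8, "angle_mean": 0.0, "angle_concentration": 0.7},
      "non_fishing": {"speed_mode_kmh": 14.0, "speed_cv": 0.25, "angle_mean": 0.0, "angle_concentration": 12.0},
      "A": [[0.9993056, 0.0006944], [0.0027778, 0.9972222]],
      "trip_duration_range_h": [12.0, 36.0],
      "min_fishing_event_s": 3600,
      "start_area": {"lat": [0.2, 1.0], "lon": [9.0, 9.5]},
      "heading_persistence": 12.0
    },
    "BG": {
      "gear": "BG",
      "label": "bottom gillnet",
      "fishing": {"speed_mode_kmh": 2.0, "speed_cv": 0.8, "angle_mean": 0.0, "angle_concentration": 0.7},
      "non_fishing": {"speed_mode_kmh": 13.0, "speed_cv": 0.25, "angle_mean": 0.0, "angle_concentration": 12.0},
      "A": [[0.9991667, 0.0008333], [0.0020833, 0.9979167]],
      "trip_duration_range_h": [12.0, 30.0],
      "min_fishing_event_s": 2400,
      "start_area": {"lat": [0.2, 1.0], "lon": [9.0, 9.5]},
      "heading_persistence": 12.0
    }
  },
  "fleet_counts": {"SCG": 10, "SG": 14, "MCG": 12, "PS": 32, "HL": 12, "LL": 8, "BG": 11}
}
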