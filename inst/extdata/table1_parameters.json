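[
  {
    "name": "cost_nivolumab",
    "mean": 14975,
    "sd": 2995,
    "kind": "gamma",
    "ci95": [9703, 21417]
  },
  {
    "name": "cost_ipilimumab",
    "mean": 11450,
    "sd": 2290,
    "kind": "gamma",
    "ci95": [7413, 16296]
  },
  {
    "name": "cost_combo",
    "mean": 26425,
    "sd": 5285,
    "kind": "gamma",
    "ci95": [17089, 37662]
  },
  {
    "name": "cost_pemetrexed",
    "mean": 7990,
    "sd": 1598,
    "kind": "gamma",
    "ci95": [5182, 11395]
  },
  {
    "name": "cost_gemcitabine",
    "mean": 118,
    "sd": 23.6,
    "kind": "gamma",
    "ci95": [76, 169]
  },
  {
    "name": "cost_cisplatin",
    "mean": 94,
    "sd": 18.8,
    "kind": "gamma",
    "ci95": [61, 134]
  },
  {
    "name": "cost_carboplatin",
    "mean": 163,
    "sd": 32.6,
    "kind": "gamma",
    "ci95": [105, 233]
  },
  {
    "name": "cost_chemo_total",
    "mean": 7929,
    "sd": 1585.8,
    "kind": "gamma",
    "ci95": [5151, 11331]
  },
  {
    "name": "cost_second_line_nivo_ipi",
    "mean": 8908,
    "sd": 1781.6,
    "kind": "gamma",
    "ci95": [5764, 12735]
  },
  {
    "name": "cost_second_line_chemo",
    "mean": 12093,
    "sd": 2418.6,
    "kind": "gamma",
    "ci95": [7824, 17255]
  },
  {
    "name": "cost_toxicity_nivo_ipi",
    "mean": 1185,
    "sd": 237,
    "kind": "gamma",
    "ci95": [767, 1695]
  },
  {
    "name": "cost_toxicity_chemo",
    "mean": 6384,
    "sd": 1276.8,
    "kind": "gamma",
    "ci95": [4139, 9127]
  },
  {
    "name": "cost_stable",
    "mean": 2166,
    "sd": 433.2,
    "kind": "gamma",
    "ci95": [1397, 3098]
  },
  {
    "name": "cost_progressed",
    "mean": 4000,
    "sd": 800,
    "kind": "gamma",
    "ci95": [2575, 5712]
  },
  {
    "name": "cost_death",
    "mean": 15957,
    "sd": 3191.4,
    "kind": "gamma",
    "ci95": [10335, 22818]
  },
  {
    "name": "cost_patient_time",
    "mean": 534,
    "sd": 106.8,
    "kind": "gamma",
    "ci95": [345, 763]
  },
  {
    "name": "cost_transport_nivo_ipi",
    "mean": 91,
    "sd": 18.2,
    "kind": "gamma",
    "ci95": [59, 130]
  },
  {
    "name": "cost_transport_chemo",
    "mean": 61,
    "sd": 12.2,
    "kind": "gamma",
    "ci95": [39, 87]
  },
  {
    "name": "cost_caregiver",
    "mean": 619,
    "sd": 123.8,
    "kind": "gamma",
    "ci95": [401, 882]
  },
  {
    "name": "cost_productivity",
    "mean": 854,
    "sd": 170.8,
    "kind": "gamma",
    "ci95": [553, 1219]
  },
  {
    "name": "utility_stable",
    "mean": 0.754,
    "sd": 0.1508,
    "kind": "beta",
    "ci95": [0.407, 0.97]
  },
  {
    "name": "utility_progression_decrement",
    "mean": 0.18,
    "sd": 0.036,
    "kind": "beta",
    "ci95": [0.115, 0.367]
  },
  {
    "name": "disutility_toxicity_nivo_ipi",
    "mean": 0.017,
    "sd": 0.0034,
    "kind": "beta",
    "ci95": [0.011, 0.024]
  },
  {
    "name": "disutility_toxicity_chemo",
    "mean": 0.019,
    "sd": 0.0038,
    "kind": "beta",
    "ci95": [0.012, 0.027]
  },
  {
    "name": "utility_death",
    "mean": 0,
    "sd": 0,
    "kind": "fixed"
  },
  {
    "name": "second_line_uptake_nivo_ipi",
    "mean": 0.377,
    "sd": 0.0754,
    "kind": "beta"
  },
  {
    "name": "second_line_uptake_chemo",
    "mean": 0.537,
    "sd": 0.1074,
    "kind": "beta"
  },
  {
    "name": "os_hazard_ratio",
    "mean": 0.73,
    "sd": 0.146,
    "kind": "fixed",
    "ci95": [0.64, 0.84]
  }
]
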