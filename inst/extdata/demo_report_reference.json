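{
  "seed": 42,
  "n_simulated": 80,
  "n_retained_cnes": 79,
  "n_rejected_blocks": 2,
  "n_dcnes": 35,
  "n_lineage_specific": 19,
  "n_convergent": 16,
  "combinations": {
    "combination": ["caecilian", "caecilian+snake", "snake", "caecilian+lizard_A+lizard_B+snake", "lizard_A+snake"],
    "n": [10, 9, 9, 4, 3]
  },
  "rates": {
    "species": ["caecilian_1", "caecilian_2", "caecilian_3", "caecilian_4", "snake_1", "snake_2", "snake_3", "snake_4", "snake_5", "snake_6", "lizard_A_1", "lizard_B_1"],
    "lineage": ["caecilian", "caecilian", "caecilian", "caecilian", "snake", "snake", "snake", "snake", "snake", "snake", "lizard_A", "lizard_B"],
    "n_convergent_dcnes": [13, 13, 13, 13, 16, 16, 16, 16, 16, 16, 7, 4],
    "rate_per_myr": [0.067708333333, 0.067708333333, 0.067708333333, 0.067708333333, 0.094117647059, 0.094117647059, 0.094117647059, 0.094117647059, 0.094117647059, 0.094117647059, 0.175, 0.11428571429]
  },
  "neutral_means": [0.99734801081, 0.92907538464, 0.9129445281],
  "neutral_max_p": 0.020606888539,
  "limb_gene_min_q": 0.001029205685,
  "region_top": "limb_E11",
  "n_limited_shared": 49,
  "mc_z": 10.634721062,
  "mc_p": 0.000199960008,
  "fraction_pleiotropic": 0.6875,
  "origin_counts": {
    "chordate_ancestor": 5,
    "gnathostome_ancestor": 4,
    "lungfish_tetrapod_ancestor": 1,
    "osteichthyan_ancestor": 1,
    "sarcopterygian_ancestor": 1,
    "tetrapod_ancestor": 2,
    "vertebrate_ancestor": 2
  }
}
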