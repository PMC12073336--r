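{
  "comment": "Synthetic beverage-market specification: per-category nutrient marginals (median, min, max per 100 mL) emulating the published category summaries of the Spanish non-alcoholic beverage market. Energy in kcal. fvl_mix_weight is the probability mass placed on the triangular component (remainder at 0%) for categories whose fruit/veg/legume percentage is strongly bimodal. The legume-based saturated-fat maximum is a reconciled transcription (printed median exceeded the printed maximum).",
  "categories": [
    {
      "category": "alcohol_substitute", "label": "Alcohol-substitute beverages", "n": 95,
      "energy_kcal": [22.0, 0.95, 72.0], "sugars_g": [2.1, 0.0, 18.0],
      "total_fat_g": [0.0, 0.0, 0.5], "satfat_g": [0.0, 0.0, 0.1],
      "salt_g": [0.01, 0.0, 0.3], "protein_g": [0.1, 0.0, 1.0],
      "fiber_g": [0.0, 0.0, 3.0], "fvl_percent": [0.0, 0.0, 24.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "artificially_sweetened", "label": "Artificially sweetened beverages", "n": 288,
      "energy_kcal": [1.0, 0.0, 16.0], "sugars_g": [0.0, 0.0, 9.0],
      "total_fat_g": [0.0, 0.0, 0.9], "satfat_g": [0.0, 0.0, 0.9],
      "salt_g": [0.02, 0.0, 0.24], "protein_g": [0.0, 0.0, 1.5],
      "fiber_g": [0.0, 0.0, 0.6], "fvl_percent": [0.0, 0.0, 35.0],
      "nns_prevalence": 1.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "sugar_sweetened", "label": "Sugar-sweetened beverages", "n": 648,
      "energy_kcal": [33.0, 0.25, 106.0], "sugars_g": [7.6, 0.0, 16.0],
      "total_fat_g": [0.0, 0.0, 1.2], "satfat_g": [0.0, 0.0, 0.5],
      "salt_g": [0.01, 0.0, 1.0], "protein_g": [0.0, 0.0, 1.17],
      "fiber_g": [0.0, 0.0, 0.7], "fvl_percent": [0.0, 0.0, 100.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "cereal_based", "label": "Cereal-based beverages", "n": 313,
      "energy_kcal": [52.0, 22.0, 106.0], "sugars_g": [6.1, 0.0, 15.2],
      "total_fat_g": [1.1, 0.0, 12.0], "satfat_g": [0.2, 0.0, 1.0],
      "salt_g": [0.09, 0.0, 0.55], "protein_g": [0.6, 0.0, 3.6],
      "fiber_g": [0.4, 0.0, 2.7], "fvl_percent": [0.0, 0.0, 29.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "legume_based", "label": "Legume-based beverages", "n": 165,
      "energy_kcal": [43.0, 25.0, 79.0], "sugars_g": [2.9, 0.0, 12.0],
      "total_fat_g": [1.8, 0.5, 2.9], "satfat_g": [0.3, 0.0, 2.7],
      "salt_g": [0.49, 0.0, 2.9], "protein_g": [3.1, 1.5, 5.0],
      "fiber_g": [0.49, 0.0, 2.9], "fvl_percent": [11.0, 0.0, 97.4],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "nut_based", "label": "Nut-based beverages", "n": 123,
      "energy_kcal": [33.0, 10.42, 85.0], "sugars_g": [2.5, 0.0, 8.0],
      "total_fat_g": [1.9, 0.2, 5.0], "satfat_g": [0.2, 0.0, 0.9],
      "salt_g": [0.1, 0.0, 0.19], "protein_g": [0.7, 0.0, 4.2],
      "fiber_g": [0.3, 0.0, 2.2], "fvl_percent": [2.8, 0.0, 96.9],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "plant_based_mix", "label": "Plant-based beverages mix", "n": 67,
      "energy_kcal": [60.0, 14.58, 83.0], "sugars_g": [5.6, 0.0, 9.0],
      "total_fat_g": [1.5, 0.4, 4.9], "satfat_g": [0.4, 0.07, 2.6],
      "salt_g": [0.1, 0.0, 0.3], "protein_g": [0.5, 0.0, 2.9],
      "fiber_g": [0.5, 0.1, 1.3], "fvl_percent": [0.02, 0.0, 15.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "milk", "label": "Milk", "n": 148,
      "energy_kcal": [46.0, 31.0, 70.8], "sugars_g": [4.7, 4.4, 7.4],
      "total_fat_g": [1.6, 0.0, 3.7], "satfat_g": [1.05, 0.0, 2.5],
      "salt_g": [0.13, 0.1, 0.2], "protein_g": [3.1, 3.0, 5.4],
      "fiber_g": [0.0, 0.0, 0.0], "fvl_percent": [0.0, 0.0, 0.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "milkshakes", "label": "Milkshakes", "n": 139,
      "energy_kcal": [45.0, 11.0, 88.0], "sugars_g": [7.5, 1.9, 13.0],
      "total_fat_g": [0.1, 0.0, 2.8], "satfat_g": [0.0, 0.0, 1.8],
      "salt_g": [0.1, 0.0, 0.25], "protein_g": [0.5, 0.0, 8.3],
      "fiber_g": [0.0, 0.0, 1.2], "fvl_percent": [3.2, 0.0, 90.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 1.0
    },
    {
      "category": "fruit_juices", "label": "Fruit juices", "n": 193,
      "energy_kcal": [48.0, 12.0, 91.0], "sugars_g": [9.2, 0.0, 15.0],
      "total_fat_g": [0.2, 0.0, 6.0], "satfat_g": [0.03, 0.0, 4.7],
      "salt_g": [0.02, 0.0, 7.0], "protein_g": [0.5, 0.0, 2.6],
      "fiber_g": [0.0, 0.0, 11.0], "fvl_percent": [99.0, 0.0, 100.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 0.8
    },
    {
      "category": "concentrates_nectars", "label": "Fruit juice concentrates and nectars", "n": 916,
      "energy_kcal": [45.0, 4.0, 95.0], "sugars_g": [9.9, 0.0, 23.0],
      "total_fat_g": [0.1, 0.0, 2.0], "satfat_g": [0.0, 0.0, 1.5],
      "salt_g": [0.01, 0.0, 0.4], "protein_g": [0.3, 0.0, 2.9],
      "fiber_g": [0.0, 0.0, 2.5], "fvl_percent": [99.0, 0.0, 100.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 0.8
    },
    {
      "category": "vegetable_juices", "label": "Vegetable juices", "n": 337,
      "energy_kcal": [40.0, 2.4, 186.0], "sugars_g": [4.1, 0.0, 19.0],
      "total_fat_g": [0.1, 0.0, 14.0], "satfat_g": [0.0, 0.0, 2.2],
      "salt_g": [0.05, 0.0, 2.0], "protein_g": [0.6, 0.0, 3.5],
      "fiber_g": [0.0, 0.0, 3.4], "fvl_percent": [54.0, 0.0, 100.0],
      "nns_prevalence": 0.0, "water_flag_prevalence": 0.0, "fvl_mix_weight": 0.8
    }
  ]
}
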