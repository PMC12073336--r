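{
  "comment": "Non-nutritive (intense) sweetener keywords matched case- and diacritic-insensitively against ingredient lists; Spanish and English label spellings plus EU E-numbers.",
  "keywords": [
    "acesulfam", "acesulfame", "aspartam", "aspartame", "ciclamato", "cyclamate",
    "sacarina", "saccharin", "sucralosa", "sucralose", "taumatina", "thaumatin",
    "neohesperidina", "neohesperidine", "estevia", "stevia", "steviol",
    "glucosidos de esteviol", "neotamo", "neotame", "advantamo", "advantame",
    "edulcorante", "sweetener",
    "e950", "e-950", "e951", "e-951", "e952", "e-952", "e954", "e-954",
    "e955", "e-955", "e957", "e-957", "e959", "e-959", "e960", "e-960",
    "e961", "e-961", "e962", "e-962", "e969", "e-969"
  ]
}
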