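{
  "trait": "alcohol",
  "note": "UNOFFICIAL placeholder: CpG identities of the published alcohol signature with synthetic placeholder coefficients; the published coefficients are not redistributed here. For format demos and tests only.",
  "cpgs": [
    {"id": "cg06690548", "coef": -1.0},
    {"id": "cg03497652", "coef": 0.5},
    {"id": "cg00716257", "coef": -0.5}
  ],
  "snps": [],
  "intercept": 0.0,
  "mu": 0.0,
  "sigma": 1.0,
  "provenance": {"source": "synthetic placeholder", "prune_alpha": 0.05}
}
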