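{
  "comment": "N-glycan tree grammars. Each production: parent component + attachment position -> child component + anomer. Position 0 denotes the root attachment to Asn ND2. depth restricts where a production applies: 1 = first NAG only, 2 = second NAG, 3 = the branching BMA, 4+ = arm mannoses and beyond (-1 = any depth at or beyond 4). All five types share the eukaryotic five-residue core. Vocabulary restricted to the supported pyranoses (no GAL/XYL/SIA).",
  "core": [
    {"parent": "ASN", "position": 0, "child": "NAG", "anomer": "beta",  "depth": 0},
    {"parent": "NAG", "position": 4, "child": "NAG", "anomer": "beta",  "depth": 1},
    {"parent": "NAG", "position": 4, "child": "BMA", "anomer": "beta",  "depth": 2},
    {"parent": "BMA", "position": 3, "child": "MAN", "anomer": "alpha", "depth": 3},
    {"parent": "BMA", "position": 6, "child": "MAN", "anomer": "alpha", "depth": 3}
  ],
  "types": {
    "high-mannose": {
      "fucoses": [
        {"parent": "NAG", "position": 6, "child": "FUC", "anomer": "alpha", "depth": 1},
        {"parent": "NAG", "position": 3, "child": "FUC", "anomer": "alpha", "depth": 1}
      ],
      "beyond_core": [
        {"parent": "MAN", "position": 2, "child": "MAN", "anomer": "alpha", "depth": -1},
        {"parent": "MAN", "position": 3, "child": "MAN", "anomer": "alpha", "depth": -1},
        {"parent": "MAN", "position": 6, "child": "MAN", "anomer": "alpha", "depth": -1}
      ]
    },
    "hybrid-mammal": {
      "fucoses": [
        {"parent": "NAG", "position": 6, "child": "FUC", "anomer": "alpha", "depth": 1}
      ],
      "beyond_core": [
        {"parent": "BMA", "position": 4, "child": "NAG", "anomer": "beta",  "depth": 3},
        {"parent": "MAN", "position": 2, "child": "NAG", "anomer": "beta",  "depth": -1},
        {"parent": "MAN", "position": 3, "child": "MAN", "anomer": "alpha", "depth": -1},
        {"parent": "MAN", "position": 6, "child": "MAN", "anomer": "alpha", "depth": -1}
      ]
    },
    "complex-mammal": {
      "fucoses": [
        {"parent": "NAG", "position": 6, "child": "FUC", "anomer": "alpha", "depth": 1}
      ],
      "beyond_core": [
        {"parent": "BMA", "position": 4, "child": "NAG", "anomer": "beta",  "depth": 3},
        {"parent": "MAN", "position": 2, "child": "NAG", "anomer": "beta",  "depth": -1},
        {"parent": "MAN", "position": 4, "child": "NAG", "anomer": "beta",  "depth": -1},
        {"parent": "MAN", "position": 6, "child": "NAG", "anomer": "beta",  "depth": -1},
        {"parent": "NAG", "position": 4, "child": "NAG", "anomer": "beta",  "depth": -1}
      ]
    },
    "hybrid-plant": {
      "fucoses": [
        {"parent": "NAG", "position": 3, "child": "FUC", "anomer": "alpha", "depth": 1}
      ],
      "beyond_core": [
        {"parent": "BMA", "position": 4, "child": "NAG", "anomer": "beta",  "depth": 3},
        {"parent": "MAN", "position": 2, "child": "NAG", "anomer": "beta",  "depth": -1},
        {"parent": "MAN", "position": 3, "child": "MAN", "anomer": "alpha", "depth": -1},
        {"parent": "MAN", "position": 6, "child": "MAN", "anomer": "alpha", "depth": -1}
      ]
    },
    "complex-plant": {
      "fucoses": [
        {"parent": "NAG", "position": 3, "child": "FUC", "anomer": "alpha", "depth": 1}
      ],
      "beyond_core": [
        {"parent": "BMA", "position": 4, "child": "NAG", "anomer": "beta",  "depth": 3},
        {"parent": "MAN", "position": 2, "child": "NAG", "anomer": "beta",  "depth": -1},
        {"parent": "MAN", "position": 4, "child": "NAG", "anomer": "beta",  "depth": -1},
        {"parent": "NAG", "position": 4, "child": "NAG", "anomer": "beta",  "depth": -1}
      ]
    }
  }
}
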