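{
  "name": "sto-3g",
  "description": "Minimal STO-3G basis; three-Gaussian expansions of Slater orbitals with standard zeta scalings.",
  "elements": {
    "H": [
      {"l": 0,
       "exp": [3.42525091, 0.62391373, 0.16885540],
       "coef": [0.15432897, 0.53532814, 0.44463454]}
    ],
    "He": [
      {"l": 0,
       "exp": [6.36242139, 1.15892300, 0.31364979],
       "coef": [0.15432897, 0.53532814, 0.44463454]}
    ],
    "C": [
      {"l": 0,
       "exp": [71.61683700, 13.04509600, 3.53051220],
       "coef": [0.15432897, 0.53532814, 0.44463454]},
      {"l": 0,
       "exp": [2.94124940, 0.68348310, 0.22228990],
       "coef": [-0.09996723, 0.39951283, 0.70011547]},
      {"l": 1,
       "exp": [2.94124940, 0.68348310, 0.22228990],
       "coef": [0.15591627, 0.60768372, 0.39195739]}
    ],
    "N": [
      {"l": 0,
       "exp": [99.10616900, 18.05231200, 4.88566020],
       "coef": [0.15432897, 0.53532814, 0.44463454]},
      {"l": 0,
       "exp": [3.78045590, 0.87849660, 0.28571440],
       "coef": [-0.09996723, 0.39951283, 0.70011547]},
      {"l": 1,
       "exp": [3.78045590, 0.87849660, 0.28571440],
       "coef": [0.15591627, 0.60768372, 0.39195739]}
    ],
    "O": [
      {"l": 0,
       "exp": [130.70932000, 23.80886100, 6.44360830],
       "coef": [0.15432897, 0.53532814, 0.44463454]},
      {"l": 0,
       "exp": [5.03315130, 1.16959610, 0.38038900],
       "coef": [-0.09996723, 0.39951283, 0.70011547]},
      {"l": 1,
       "exp": [5.03315130, 1.16959610, 0.38038900],
       "coef": [0.15591627, 0.60768372, 0.39195739]}
    ]
  }
}
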