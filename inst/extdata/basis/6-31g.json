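{
  "name": "6-31g",
  "description": "Split-valence 6-31G basis for first-row elements and hydrogen.",
  "elements": {
    "H": [
      {"l": 0,
       "exp": [18.73113700, 2.82539370, 0.64012170],
       "coef": [0.03349460, 0.23472695, 0.81375733]},
      {"l": 0, "exp": [0.16127780], "coef": [1.0]}
    ],
    "C": [
      {"l": 0,
       "exp": [3047.52490, 457.36951, 103.94869, 29.21015500, 9.28666300, 3.16392700],
       "coef": [0.00183470, 0.01403730, 0.06884260, 0.23218440, 0.46794130, 0.36231200]},
      {"l": 0,
       "exp": [7.86827240, 1.88128850, 0.54424930],
       "coef": [-0.11933240, -0.16085420, 1.14345640]},
      {"l": 1,
       "exp": [7.86827240, 1.88128850, 0.54424930],
       "coef": [0.06899910, 0.31642400, 0.74430830]},
      {"l": 0, "exp": [0.16871440], "coef": [1.0]},
      {"l": 1, "exp": [0.16871440], "coef": [1.0]}
    ],
    "N": [
      {"l": 0,
       "exp": [4173.51100, 627.45790, 142.90210, 40.23433000, 12.82021000, 4.39043700],
       "coef": [0.00183480, 0.01399500, 0.06858700, 0.23224100, 0.46907000, 0.36045500]},
      {"l": 0,
       "exp": [11.62635800, 2.71628000, 0.77221800],
       "coef": [-0.11496100, -0.16911800, 1.14585200]},
      {"l": 1,
       "exp": [11.62635800, 2.71628000, 0.77221800],
       "coef": [0.06758000, 0.32390700, 0.74089500]},
      {"l": 0, "exp": [0.21203130], "coef": [1.0]},
      {"l": 1, "exp": [0.21203130], "coef": [1.0]}
    ],
    "O": [
      {"l": 0,
       "exp": [5484.67170, 825.23495, 188.04696, 52.96450000, 16.89757000, 5.79963530],
       "coef": [0.00183110, 0.01395010, 0.06844510, 0.23271430, 0.47019300, 0.35852090]},
      {"l": 0,
       "exp": [15.53961600, 3.59993360, 1.01376180],
       "coef": [-0.11077750, -0.14802630, 1.13076700]},
      {"l": 1,
       "exp": [15.53961600, 3.59993360, 1.01376180],
       "coef": [0.07087430, 0.33975280, 0.72715860]},
      {"l": 0, "exp": [0.27000580], "coef": [1.0]},
      {"l": 1, "exp": [0.27000580], "coef": [1.0]}
    ]
  }
}
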