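seed: 42.0
synthesis:
  nrows: 200.0
  ncols: 200.0
  cellsize: 10.0
  fractions:
    agriculture: 0.2044
    forest: 0.4359
    settlement: 0.2725
    water: 0.0872
  smoothing: 5.0
  transition:
    agriculture:
      agriculture: 1.0
      forest: 0.0
      settlement: 0.0
      water: 0.0
    forest:
      agriculture: 0.0056872
      forest: 0.7803242
      settlement: 0.1891518
      water: 0.0248368
    settlement:
      agriculture: 0.0
      forest: 0.0
      settlement: 1.0
      water: 0.0
    water:
      agriculture: 0.0
      forest: 0.0
      settlement: 0.0
      water: 1.0
  mode: frontier
  covariates:
    lst:
      mean:
        agriculture: 28.0
        forest: 25.0
        settlement: 32.0
        water: 22.0
      sd:
        agriculture: 1.0
        forest: 1.0
        settlement: 1.0
        water: 1.0
      units: degC
    population:
      mean:
        agriculture: 5.0
        forest: 1.0
        settlement: 50.0
        water: 0.5
      sd:
        agriculture: 1.5
        forest: 0.4
        settlement: 10.0
        water: 0.2
      units: persons/cell
    carbon:
      mean:
        agriculture: 5.0
        forest: 0.5
        settlement: 10.0
        water: 1.0
      sd:
        agriculture: 1.0
        forest: 0.2
        settlement: 2.0
        water: 0.3
      units: t/ha
  reference:
    'n': 600.0
    error_rate: 0.05
membership:
  functions: linear_small
  covariates: large
  spread: 5.0
combine:
  operator: gamma
  gamma: 0.9
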