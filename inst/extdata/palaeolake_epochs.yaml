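# Example time-stratified dispersal configuration for the 12
# hydrological sub-basins (areas A-L).  During the Pleistocene palaeolake
# phase (2.5-0.01 Ma) dispersal among the palaeolake-connected areas
# (C, D, E, F, G and Cotija J) is elevated x5; this multiplier is a
# package default illustrating the mechanism, not an empirical estimate.
areas: [A, B, C, D, E, F, G, H, I, J, K, L]
max_range_size: 2
epoch_boundaries: [2.5, 0.01, 0]
multipliers:
  # pre-palaeolake epoch (> 2.5 Ma): uniform dispersal
  -
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
  # palaeolake epoch (2.5 - 0.01 Ma): elevated among lake areas
  -
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 5, 5, 5, 5, 1, 1, 5, 1, 1]
    - [1, 1, 5, 1, 5, 5, 5, 1, 1, 5, 1, 1]
    - [1, 1, 5, 5, 1, 5, 5, 1, 1, 5, 1, 1]
    - [1, 1, 5, 5, 5, 1, 5, 1, 1, 5, 1, 1]
    - [1, 1, 5, 5, 5, 5, 1, 1, 1, 5, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 5, 5, 5, 5, 5, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
  # modern epoch (< 0.01 Ma): uniform dispersal
  -
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
    - [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
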