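# Weather Prediction Task contingency structure: all 14 combinations of
# one to three of the four cards, with presentation frequencies and the
# conditional probability of the "sun" outcome.
#
# provenance: external-literature.  The 14-pattern structure and the
# frequency column follow the classic probabilistic-classification
# design (Knowlton, Squire & Gluck 1994); the three anchor
# probabilities P(sun|{1,2}) = 0.90, P(sun|{1,2,3}) = 0.79 and
# P(sun|{4}) = 0.15 are fixed by the source figure, and the remaining
# entries follow the published task.  The two combinations with
# P(sun) = 0.50 are flagged for exclusion from analysis (they are still
# trained).
combinations:
  - cards: [4]
    freq: 0.14
    p_sun: 0.15
  - cards: [3]
    freq: 0.08
    p_sun: 0.38
  - cards: [3, 4]
    freq: 0.09
    p_sun: 0.10
  - cards: [2]
    freq: 0.08
    p_sun: 0.62
  - cards: [2, 4]
    freq: 0.06
    p_sun: 0.18
  - cards: [2, 3]
    freq: 0.06
    p_sun: 0.50
  - cards: [2, 3, 4]
    freq: 0.04
    p_sun: 0.21
  - cards: [1]
    freq: 0.14
    p_sun: 0.85
  - cards: [1, 4]
    freq: 0.06
    p_sun: 0.50
  - cards: [1, 3]
    freq: 0.06
    p_sun: 0.82
  - cards: [1, 3, 4]
    freq: 0.03
    p_sun: 0.43
  - cards: [1, 2]
    freq: 0.09
    p_sun: 0.90
  - cards: [1, 2, 3]
    freq: 0.04
    p_sun: 0.79
  - cards: [1, 2, 4]
    freq: 0.03
    p_sun: 0.60
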