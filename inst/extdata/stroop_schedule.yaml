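# Stroop test timing: one row per (phase, words-per-slide) block.
# Phases run BLACK -> CONGRUENT -> INCONGRUENT; 24 word slides, 85 s total.
- {phase: BLACK, words: 3, n_slides: 2, seconds: 2}
- {phase: BLACK, words: 4, n_slides: 2, seconds: 2.5}
- {phase: BLACK, words: 5, n_slides: 1, seconds: 3}
- {phase: BLACK, words: 6, n_slides: 1, seconds: 3.5}
- {phase: CONGRUENT, words: 3, n_slides: 2, seconds: 2}
- {phase: CONGRUENT, words: 4, n_slides: 2, seconds: 2.5}
- {phase: CONGRUENT, words: 5, n_slides: 1, seconds: 3}
- {phase: CONGRUENT, words: 6, n_slides: 1, seconds: 3.5}
- {phase: INCONGRUENT, words: 3, n_slides: 2, seconds: 2.5}
- {phase: INCONGRUENT, words: 4, n_slides: 2, seconds: 3}
- {phase: INCONGRUENT, words: 5, n_slides: 2, seconds: 3.5}
- {phase: INCONGRUENT, words: 6, n_slides: 2, seconds: 4}
- {phase: INCONGRUENT, words: 9, n_slides: 2, seconds: 6}
- {phase: INCONGRUENT, words: 12, n_slides: 2, seconds: 8}
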