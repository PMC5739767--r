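# Default SIM fragment registry for the [1,2-13C2]-glucose tracing workflow.
#
# Formulas are the ions implied by the derivatization chemistry used for each
# metabolite (aldononitrile acetates for glucose and ribose, heptafluorobutyryl
# propylamide for lactate, N-TFA butyl ester for alanine, methyl esters for
# the fatty acids) under chemical ionization; they are editable defaults,
# validated against the recorded m/z window (monoisotopic mass must fall in
# [mz_low - 1, mz_high]).
#
# n_carbons: carbons of the biological backbone carried by the fragment.
glucose:
  formula: {C: 14, H: 18, "N": 1, O: 8}
  n_carbons: 6
  mz_low: 327
  mz_high: 336
lactate:
  formula: {C: 10, H: 12, F: 7, "N": 1, O: 3}
  n_carbons: 3
  mz_low: 327
  mz_high: 332
alanine:
  formula: {C: 9, H: 14, F: 3, "N": 1, O: 3}
  n_carbons: 3
  mz_low: 241
  mz_high: 246
ribose:
  formula: {C: 11, H: 14, "N": 1, O: 6}
  n_carbons: 5
  mz_low: 256
  mz_high: 261
palmitate:
  formula: {C: 17, H: 34, O: 2}
  n_carbons: 16
  mz_low: 269
  mz_high: 278
stearate:
  formula: {C: 19, H: 38, O: 2}
  n_carbons: 18
  mz_low: 297
  mz_high: 307
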