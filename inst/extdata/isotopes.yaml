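# Natural isotopic abundances (IUPAC representative values).
# offset: nominal mass shift relative to the most abundant (lightest) isotope.
C:
  - {offset: 0, mass: 12.000000, abundance: 0.98930}
  - {offset: 1, mass: 13.003355, abundance: 0.01070}
H:
  - {offset: 0, mass: 1.007825, abundance: 0.999885}
  - {offset: 1, mass: 2.014102, abundance: 0.000115}
"N":
  - {offset: 0, mass: 14.003074, abundance: 0.99636}
  - {offset: 1, mass: 15.000109, abundance: 0.00364}
O:
  - {offset: 0, mass: 15.994915, abundance: 0.99757}
  - {offset: 1, mass: 16.999132, abundance: 0.00038}
  - {offset: 2, mass: 17.999160, abundance: 0.00205}
F:
  - {offset: 0, mass: 18.998403, abundance: 1.0}
Si:
  - {offset: 0, mass: 27.976927, abundance: 0.92223}
  - {offset: 1, mass: 28.976495, abundance: 0.04685}
  - {offset: 2, mass: 29.973770, abundance: 0.03092}
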