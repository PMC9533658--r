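# IPCI scoring configuration, version 1.
#
# Metric value ranges mapped to ordinal scores {0, 4, 7, 11} for the two
# prairie-pothole hydrologic classes, and total-score ranges for the
# condition categories. Ranges are inclusive at both ends and stated at
# each metric's printed precision (counts: integer; percentage: 1
# decimal; average C and FQI: 2 decimals); values are rounded half away
# from zero to that precision before lookup. Adapting the index to
# another region means editing this file, not the code.
version: 1
scores: [0, 4, 7, 11]
metric_precision:
  richness_native_perennial: 0
  genera_native_perennial: 0
  native_grass_grasslike: 0
  pct_annual_biennial_introduced: 1
  wetmeadow_native_perennial: 0
  count_c_ge_5: 0
  wetmeadow_count_c_ge_4: 0
  avg_c: 2
  fqi: 2
metrics:
  temporarily_ponded:
    richness_native_perennial:
      - {score: 0, min: 0, max: 16}
      - {score: 4, min: 17, max: 23}
      - {score: 7, min: 24, max: 40}
      - {score: 11, min: 41, max: .inf}
    genera_native_perennial:
      - {score: 0, min: 0, max: 11}
      - {score: 4, min: 12, max: 19}
      - {score: 7, min: 20, max: 26}
      - {score: 11, min: 27, max: .inf}
    native_grass_grasslike:
      - {score: 0, min: 0, max: 8}
      - {score: 4, min: 9, max: 10}
      - {score: 7, min: 11, max: 15}
      - {score: 11, min: 16, max: .inf}
    pct_annual_biennial_introduced:
      - {score: 0, min: 41.1, max: .inf}
      - {score: 4, min: 35.1, max: 41.0}
      - {score: 7, min: 27.1, max: 35.0}
      - {score: 11, min: 0.0, max: 27.0}
    wetmeadow_native_perennial:
      - {score: 0, min: 0, max: 7}
      - {score: 4, min: 8, max: 10}
      - {score: 7, min: 11, max: 13}
      - {score: 11, min: 14, max: .inf}
    count_c_ge_5:
      - {score: 0, min: 0, max: 4}
      - {score: 4, min: 5, max: 11}
      - {score: 7, min: 12, max: 16}
      - {score: 11, min: 17, max: .inf}
    wetmeadow_count_c_ge_4:
      - {score: 0, min: 0, max: 3}
      - {score: 4, min: 4, max: 9}
      - {score: 7, min: 10, max: 12}
      - {score: 11, min: 13, max: .inf}
    avg_c:
      - {score: 0, min: 0.00, max: 2.50}
      - {score: 4, min: 2.51, max: 3.57}
      - {score: 7, min: 3.58, max: 4.58}
      - {score: 11, min: 4.59, max: .inf}
    fqi:
      - {score: 0, min: 0.00, max: 13.60}
      - {score: 4, min: 13.61, max: 21.70}
      - {score: 7, min: 21.71, max: 27.20}
      - {score: 11, min: 27.21, max: .inf}
  seasonally_ponded:
    richness_native_perennial:
      - {score: 0, min: 0, max: 19}
      - {score: 4, min: 20, max: 31}
      - {score: 7, min: 32, max: 41}
      - {score: 11, min: 42, max: .inf}
    genera_native_perennial:
      - {score: 0, min: 0, max: 14}
      - {score: 4, min: 15, max: 24}
      - {score: 7, min: 25, max: 32}
      - {score: 11, min: 33, max: .inf}
    native_grass_grasslike:
      - {score: 0, min: 0, max: 6}
      - {score: 4, min: 7, max: 10}
      - {score: 7, min: 11, max: 17}
      - {score: 11, min: 18, max: .inf}
    pct_annual_biennial_introduced:
      - {score: 0, min: 41.1, max: .inf}
      - {score: 4, min: 30.8, max: 41.0}
      - {score: 7, min: 21.1, max: 30.7}
      - {score: 11, min: 0.0, max: 21.0}
    wetmeadow_native_perennial:
      - {score: 0, min: 0, max: 8}
      - {score: 4, min: 9, max: 16}
      - {score: 7, min: 17, max: 24}
      - {score: 11, min: 25, max: .inf}
    count_c_ge_5:
      - {score: 0, min: 0, max: 7}
      - {score: 4, min: 8, max: 17}
      - {score: 7, min: 18, max: 26}
      - {score: 11, min: 27, max: .inf}
    wetmeadow_count_c_ge_4:
      - {score: 0, min: 0, max: 4}
      - {score: 4, min: 5, max: 9}
      - {score: 7, min: 10, max: 16}
      - {score: 11, min: 17, max: .inf}
    avg_c:
      - {score: 0, min: 0.00, max: 2.60}
      - {score: 4, min: 2.61, max: 3.12}
      - {score: 7, min: 3.13, max: 3.52}
      - {score: 11, min: 3.53, max: .inf}
    fqi:
      - {score: 0, min: 0.00, max: 10.00}
      - {score: 4, min: 10.01, max: 16.11}
      - {score: 7, min: 16.12, max: 22.99}
      - {score: 11, min: 23.00, max: .inf}
categories:
  temporarily_ponded:
    - {category: Poor, min: 0, max: 33}
    - {category: Fair, min: 34, max: 66}
    - {category: Good, min: 67, max: 99}
  seasonally_ponded:
    - {category: Very poor, min: 0, max: 19}
    - {category: Poor, min: 20, max: 39}
    - {category: Fair, min: 40, max: 59}
    - {category: Good, min: 60, max: 79}
    - {category: Very good, min: 80, max: 99}
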