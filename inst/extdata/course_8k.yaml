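# Trail Valle de Tena, 8K modality (ultra distance), 2017-2019 course.
# Shares the same five timed sections as the 4K. The published downhill race
# factor is 148 (raw totals give 147.5); kept as an explicit override so the
# published relative-difficulty table reproduces exactly.
name: "8K"
distance_km: 78
gain_m: 6900
loss_m: 6950
idf_neg: 148
sections:
  - {index: 1, start_cp: cp0, end_cp: cp1, distance_km: 5.5, gain_m: 1430, loss_m: 10, net_slope: positive, idf_override: 20.5}
  - {index: 2, start_cp: cp1, end_cp: cp2, distance_km: 5.5, gain_m: 205, loss_m: 1150, net_slope: negative}
  - {index: 3, start_cp: cp2, end_cp: cp3, distance_km: 5.5, gain_m: 650, loss_m: 80, net_slope: positive}
  - {index: 4, start_cp: cp3, end_cp: cp4, distance_km: 4.0, gain_m: 75, loss_m: 680, net_slope: negative, idf_override: 11.0}
  - {index: 5, start_cp: cp4, end_cp: cp5, distance_km: 4.0, gain_m: 470, loss_m: 75, net_slope: positive, idf_override: 9.0}
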