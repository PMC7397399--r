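# Published acquisition method for the kava VOC dual-channel runs:
# 2.5 s modulation (100 ms flush), FID at 120 Hz, quadrupole scanning
# 40-300 m/z in 0.0241 s (41.5 scans/s), effluent split ~4.5:1 FID:MS,
# oven 60 C (1 min) -> 250 C at 5 C/min (10 min); 49 min total.
modulation_period: 2.5
flush_time: 100
fid_rate: 120
ms_scan_time: 0.0241
mz_min: 40
mz_max: 300
split_ratio_fid_to_ms: 4.5
oven:
  initial_temp: 60
  initial_hold: 1
  ramp_rate: 5
  final_temp: 250
  final_hold: 10
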