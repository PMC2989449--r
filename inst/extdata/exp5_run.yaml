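# Example run configuration: the mediating-behavior probe session.
# 12 intact subjects, one 48-trial session each at the largest
# separations, 6 s delay, 20 s inter-trial interval.
experiment: exp5
seed: 2024
profiles:
  sham:
    p_max: 0.88
    tau_s: 60
    sep_floor: 2
    sep_scale: 1.5
  sham_toucher:
    p_max: 0.88
    tau_s: 60
    sep_floor: 2
    sep_scale: 1.5
    strategy:
      behavior_label: screen_touch_sample
      emission_prob: 0.3
      benefit_beta: 0.0
subjects: [sham, sham, sham, sham, sham, sham,
           sham_toucher, sham_toucher, sham_toucher,
           sham_toucher, sham_toucher, sham_toucher]
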