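# Example cohort specification: a small two-group child study with a
# criterion gap and equal sensitivity. Fields not listed fall back to the
# package defaults for the same group name; [mean, sd] pairs.
child_NT:
  n: 20
  lam: [1.63, 0.19]
child_ASD:
  n: 30
  lam: [2.04, 0.27]
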