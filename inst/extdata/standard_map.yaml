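# Internal-standard configuration: rule tag -> spiked standard and its
# concentration; unidentified peaks dispatch by retention time (seconds).
standards:
  monoacyl:
    standard_id: "PC(17:0/0:0)"
    concentration: 1.0
  diacyl:
    standard_id: "PC(17:0/17:0)"
    concentration: 1.0
  ceramide:
    standard_id: "Cer(d18:1/17:0)"
    concentration: 1.0
  ethanolamine:
    standard_id: "PE(17:0/17:0)"
    concentration: 1.0
  tg_sterol:
    standard_id: "TG(17:0/17:0/17:0)"
    concentration: 1.0
rt_rules:
  - rt_upper: 300
    standard_id: "PC(17:0/0:0)"
    inclusive: false
  - rt_upper: 410
    standard_id: "PC(17:0/17:0)"
    inclusive: true
  - rt_upper: .inf
    standard_id: "TG(17:0/17:0/17:0)"
    inclusive: true
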