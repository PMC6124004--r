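obgyn_ward:
  nurse:
    morning: 3
    evening: 2
    night: 2
  fwv:
    morning: 3
    evening: 2
    night: 2
pediatric_ward:
  nurse:
    morning: 3
    evening: 2
    night: 2
operating_theatre:
  nurse:
    morning: 2
    evening: 2
    night: 2
'*':
  support:
    morning: 2
    evening: 2
    night: 2
  doctor:
    morning: 1
    evening: 1
    night: 1
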