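n_days: 30
seed: 1
entries:
- facility: MCWC
  department: obgyn_ward
  cadre: fwv
  mode: graded_headcount
  shift: morning
  counts:
    '3': 27.0
    '2': 2.0
    '1': 1.0
- facility: MCWC
  department: obgyn_ward
  cadre: fwv
  mode: graded_headcount
  shift: evening
  counts:
    '3': 5.0
    '2': 15.0
    '1': 10.0
- facility: MCWC
  department: obgyn_ward
  cadre: fwv
  mode: graded_headcount
  shift: night
  counts:
    '3': 1.0
    '2': 11.0
    '1': 17.0
    '0': 1.0
- facility: MCWC
  department: operating_theatre
  cadre: ana
  mode: doctor_style
  shift: morning
  counts:
    present_majority: 27.0
    offsite_no_call: 3.0
- facility: MCWC
  department: operating_theatre
  cadre: ana
  mode: doctor_style
  shift: evening
  counts:
    present_majority: 13.0
    offsite_no_call: 17.0
- facility: MCWC
  department: operating_theatre
  cadre: ana
  mode: doctor_style
  shift: night
  counts:
    present_majority: 17.0
    offsite_no_call: 13.0
- facility: MCWC
  department: facility
  cadre: support
  mode: support_pool
  shift: morning
  counts:
    '2': 30.0
- facility: MCWC
  department: facility
  cadre: support
  mode: support_pool
  shift: evening
  counts:
    '2': 22.0
    '1': 8.0
- facility: MCWC
  department: facility
  cadre: support
  mode: support_pool
  shift: night
  counts:
    '2': 27.0
    '1': 3.0
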