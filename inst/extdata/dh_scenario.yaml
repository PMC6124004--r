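n_days: 30
seed: 1
entries:
- facility: DH
  department: obgyn_ward
  cadre: nurse
  mode: graded_headcount
  shift: morning
  counts:
    '3': 29.0
    '2': 1.0
- facility: DH
  department: obgyn_ward
  cadre: nurse
  mode: graded_headcount
  shift: evening
  counts:
    '3': 8.0
    '2': 21.0
    '1': 1.0
- facility: DH
  department: obgyn_ward
  cadre: nurse
  mode: graded_headcount
  shift: night
  counts:
    '3': 2.0
    '2': 22.0
    '1': 6.0
- facility: DH
  department: pediatric_ward
  cadre: nurse
  mode: graded_headcount
  shift: morning
  counts:
    '3': 4.0
    '2': 20.0
    '1': 6.0
- facility: DH
  department: pediatric_ward
  cadre: nurse
  mode: graded_headcount
  shift: evening
  counts:
    '2': 7.0
    '1': 23.0
- facility: DH
  department: pediatric_ward
  cadre: nurse
  mode: graded_headcount
  shift: night
  counts:
    '2': 12.0
    '1': 18.0
- facility: DH
  department: operating_theatre
  cadre: nurse
  mode: graded_headcount_with_oncall
  shift: morning
  counts:
    '2': 25.0
    '1': 2.0
    none: 3.0
- facility: DH
  department: operating_theatre
  cadre: nurse
  mode: graded_headcount_with_oncall
  shift: evening
  counts:
    oncall_1: 4.0
    none: 26.0
- facility: DH
  department: operating_theatre
  cadre: nurse
  mode: graded_headcount_with_oncall
  shift: night
  counts:
    none: 30.0
- facility: DH
  department: laboratory
  cadre: med_technologist
  mode: doctor_style
  shift: morning
  counts:
    present_majority: 27.0
    offsite_responded: 2.0
    offsite_no_call: 1.0
- facility: DH
  department: laboratory
  cadre: med_technologist
  mode: doctor_style
  shift: evening
  counts:
    offsite_responded: 25.0
    offsite_no_call: 5.0
- facility: DH
  department: laboratory
  cadre: med_technologist
  mode: doctor_style
  shift: night
  counts:
    offsite_responded: 22.0
    offsite_no_call: 8.0
- facility: DH
  department: emergency
  cadre: doctor
  mode: doctor_style
  shift: morning
  counts:
    present_majority: 30.0
- facility: DH
  department: emergency
  cadre: doctor
  mode: doctor_style
  shift: evening
  counts:
    present_majority: 30.0
- facility: DH
  department: emergency
  cadre: doctor
  mode: doctor_style
  shift: night
  counts:
    present_majority: 30.0
- facility: DH
  department: facility
  cadre: support
  mode: support_pool
  shift: morning
  counts:
    '2': 30.0
- facility: DH
  department: facility
  cadre: support
  mode: support_pool
  shift: evening
  counts:
    '2': 30.0
- facility: DH
  department: facility
  cadre: support
  mode: support_pool
  shift: night
  counts:
    '2': 24.0
    '1': 6.0
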