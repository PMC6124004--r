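# Sanctioned posts vs staff in position at the two example facilities.
# Static metadata for context only: no index computation uses these numbers.
# in_position can exceed post where providers were borrowed from other
# facilities; project-funded nurses have no sanctioned post.
DH:
  consultant_obgyn: {post: 1, in_position: 1}
  consultant_anesthesia: {post: 1, in_position: 0}
  consultant_pediatrics: {post: 1, in_position: 2}
  anesthetist_medical_officer: {post: 1, in_position: 1}
  resident_medical_officer: {post: 2, in_position: 2}
  pathologist: {post: 1, in_position: 1}
  emergency_medical_officer: {post: 3, in_position: 1}
  medical_officer_outpatients: {post: 14, in_position: 7}
  medical_officer_trained: {post: 0, in_position: 1}
  senior_staff_nurse: {post: 38, in_position: 31}
  staff_nurse_project: {post: 0, in_position: 10}
  medical_technologist_laboratory: {post: 1, in_position: 2}
  peon_ward_boy: {post: 17, in_position: 18}
  guard: {post: 4, in_position: 1}
  aya_maid: {post: 10, in_position: 7}
  sweeper: {post: 19, in_position: 13}
MCWC:
  medical_officer_trained: {post: 1, in_position: 1}
  anesthetist_medical_officer: {post: 1, in_position: 1}
  staff_nurse_project: {post: 0, in_position: 1}
  fwv: {post: 1, in_position: 6}
  ana_dai_nurse: {post: 2, in_position: 3}
  peon_ward_boy: {post: 1, in_position: 2}
  guard: {post: 0, in_position: 2}
  aya_maid: {post: 0, in_position: 1}
  sweeper: {post: 1, in_position: 3}
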