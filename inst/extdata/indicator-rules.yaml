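# Shipped heuristic segmentation indicators: one rule per placement and
# dividing point (the mixed acceleration/angular-velocity winners), plus
# the wrist single-modality rule sets used for the modality comparison.
# Windows are relative to the impact proxy, in seconds.
- placement: wrist
  point: ADD
  source: gyro
  channel: "y"
  event: min
- placement: wrist
  point: BST
  source: gyro
  channel: "z"
  event: zero_crossing
  slope: either
- placement: wrist
  point: IMP
  source: gyro
  channel: "y"
  event: min
- placement: wrist
  point: FIN
  source: gyro
  channel: "norm"
  event: min
- placement: head
  point: ADD
  source: gyro
  channel: "norm"
  event: min
- placement: head
  point: BST
  source: acc
  channel: "x"
  event: min
- placement: head
  point: IMP
  source: acc
  channel: "norm"
  event: min
- placement: head
  point: FIN
  source: gyro
  channel: "norm"
  event: min
- placement: waist
  point: ADD
  source: gyro
  channel: "y"
  event: min
- placement: waist
  point: BST
  source: gyro
  channel: "y"
  event: zero_crossing
  slope: either
- placement: waist
  point: IMP
  source: acc
  channel: "x"
  event: zero_crossing
  slope: either
- placement: waist
  point: FIN
  source: gyro
  channel: "norm"
  event: min
# wrist, angular velocity only
- placement: wrist
  point: ADD
  source: gyro
  channel: "y"
  event: min
  modality_set: gyro
- placement: wrist
  point: BST
  source: gyro
  channel: "z"
  event: zero_crossing
  slope: either
  modality_set: gyro
- placement: wrist
  point: IMP
  source: gyro
  channel: "y"
  event: min
  modality_set: gyro
- placement: wrist
  point: FIN
  source: gyro
  channel: "norm"
  event: min
  modality_set: gyro
# wrist, acceleration only
- placement: wrist
  point: ADD
  source: acc
  channel: "y"
  event: min
  modality_set: acc
- placement: wrist
  point: BST
  source: acc
  channel: "x"
  event: min
  modality_set: acc
- placement: wrist
  point: IMP
  source: acc
  channel: "norm"
  event: max
  modality_set: acc
- placement: wrist
  point: FIN
  source: acc
  channel: "norm"
  event: min
  modality_set: acc
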