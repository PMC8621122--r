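# Bone-embedded frame for the proximal bone (label 1) of the default
# synthetic joint phantom.
bone_label: 1
origin: bone1_center
axis_a:
  from: bone1_distal
  to: bone1_proximal
  axis: k
plane:
  landmark: bone1_lateral
  axis: i
handedness: 1.0
sign_mask:
- 1.0
- 1.0
- 1.0
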