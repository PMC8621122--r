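# Bone-embedded frame for the distal bone (label 2) of the default
# synthetic joint phantom. Long axis from the distal to the proximal apex
# is k; the lateral surface point closes the plane and assigns i.
bone_label: 2
origin: bone2_center
axis_a:
  from: bone2_distal
  to: bone2_proximal
  axis: k
plane:
  landmark: bone2_lateral
  axis: i
handedness: 1.0
sign_mask:
- 1.0
- 1.0
- 1.0
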