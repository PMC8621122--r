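# Editable first-metacarpal (proximal segment) frame for thumb-base
# kinematics, using the style of landmarks placed on the thumb atlases
# (most distal point of the metacarpal, ulnar tubercle at its base).
bone_label: 1
origin: mc1_base_center
axis_a:
  from: mc1_base_center
  to: mc1_distal_point
  axis: k
plane:
  landmark: mc1_ulnar_tubercle
  axis: i
handedness: 1.0
sign_mask:
- 1.0
- 1.0
- 1.0
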