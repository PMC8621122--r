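# Editable trapezium (distal segment, per the joint convention used for
# the thumb base) frame.
bone_label: 2
origin: trapezium_center
axis_a:
  from: trapezium_center
  to: trapezium_dorsal_point
  axis: k
plane:
  landmark: trapezium_radial_point
  axis: i
handedness: 1.0
sign_mask:
- 1.0
- 1.0
- 1.0
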