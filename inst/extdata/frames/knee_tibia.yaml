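# Editable tibial (distal segment) frame for tibiofemoral kinematics.
# The centre of the tibial articular surface anchors the origin; the
# long axis runs toward the distal tibia; the intercondylar eminence /
# lateral plateau point closes the plane.
bone_label: 2
origin: tibia_articular_surface_center
axis_a:
  from: tibia_distal_center
  to: tibia_articular_surface_center
  axis: k
plane:
  landmark: tibia_lateral_plateau
  axis: i
handedness: 1.0
sign_mask:
- 1.0
- 1.0
- 1.0
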