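# Editable femoral (proximal segment) frame for tibiofemoral kinematics.
# Landmark names follow the anatomical points used for automated knee
# analysis: medial/lateral epicondyles span the flexion axis, and the most
# inferior point of the centre of the condyle (a substitute for the
# diaphysis axis point, which image cropping can place outside the field
# of view) fixes the long axis. Adjust names/axes to the atlas at hand;
# ISB axis assignment: k along the long axis, i in the sagittal plane.
bone_label: 1
origin: femur_condyle_center_inferior
axis_a:
  from: femur_condyle_center_inferior
  to: femur_head_center
  axis: k
plane:
  landmark: femur_lateral_epicondyle
  axis: i
handedness: 1.0
sign_mask:
- 1.0
- 1.0
- 1.0
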