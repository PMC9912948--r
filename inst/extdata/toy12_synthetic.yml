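name: toy12-4mus
dof:
  name:
  - pelvis_tx
  - pelvis_ty
  - pelvis_tz
  - pelvis_rot
  - pelvis_obl
  - pelvis_tilt
  - hip_yaw_r
  - hip_pitch_r
  - knee_pitch_r
  - hip_yaw_l
  - hip_pitch_l
  - knee_pitch_l
  parent:
  - 0
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  - 7
  - 8
  - 6
  - 10
  - 11
  jtype:
  - 0
  - 0
  - 0
  - 1
  - 1
  - 1
  - 1
  - 1
  - 1
  - 1
  - 1
  - 1
  axis:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 1.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 1.0
  trans:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -0.1
  - 0.12
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -0.45
  - 0.0
  - 0.0
  - -0.1
  - -0.12
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -0.45
  - 0.0
body:
  name:
  - trunk
  - thigh_r
  - shank_r
  - thigh_l
  - shank_l
  dof:
  - 6
  - 8
  - 9
  - 11
  - 12
  mass:
  - 50.0
  - 8.0
  - 5.0
  - 8.0
  - 5.0
  com:
  - 0.0
  - 0.25
  - 0.0
  - 0.0
  - -0.2
  - 0.0
  - 0.0
  - -0.25
  - 0.0
  - 0.0
  - -0.2
  - 0.0
  - 0.0
  - -0.25
  - 0.0
  inertia:
  - 3.0716667
  - 0.0
  - 0.0
  - 0.0
  - 0.81
  - 0.0
  - 0.0
  - 0.0
  - 3.0716667
  - 0.1422
  - 0.0
  - 0.0
  - 0.0
  - 0.0144
  - 0.0
  - 0.0
  - 0.0
  - 0.1422
  - 0.1072917
  - 0.0
  - 0.0
  - 0.0
  - 0.00625
  - 0.0
  - 0.0
  - 0.0
  - 0.1072917
  - 0.1422
  - 0.0
  - 0.0
  - 0.0
  - 0.0144
  - 0.0
  - 0.0
  - 0.0
  - 0.1422
  - 0.1072917
  - 0.0
  - 0.0
  - 0.0
  - 0.00625
  - 0.0
  - 0.0
  - 0.0
  - 0.1072917
markers:
  name:
  - SACR
  - LASI
  - RASI
  - STRN
  - RTHI
  - RKNE
  - LTHI
  - LKNE
  - RANK
  - RTOE
  - RHEE
  - LANK
  - LTOE
  - LHEE
  dof:
  - 6
  - 6
  - 6
  - 6
  - 8
  - 8
  - 11
  - 11
  - 9
  - 9
  - 9
  - 12
  - 12
  - 12
  local:
  - -0.12
  - 0.05
  - 0.0
  - 0.1
  - 0.03
  - -0.12
  - 0.1
  - 0.03
  - 0.12
  - 0.1
  - 0.35
  - 0.0
  - 0.06
  - -0.25
  - 0.08
  - 0.02
  - -0.44
  - 0.08
  - 0.06
  - -0.25
  - -0.08
  - 0.02
  - -0.44
  - -0.08
  - 0.0
  - -0.42
  - 0.08
  - 0.13
  - -0.47
  - 0.04
  - -0.1
  - -0.47
  - 0.0
  - 0.0
  - -0.42
  - -0.08
  - 0.13
  - -0.47
  - -0.04
  - -0.1
  - -0.47
  - 0.0
contacts:
  dof:
  - 9
  - 9
  - 9
  - 9
  - 12
  - 12
  - 12
  - 12
  foot:
  - 0
  - 0
  - 0
  - 0
  - 1
  - 1
  - 1
  - 1
  local:
  - 0.12
  - -0.48
  - 0.05
  - 0.12
  - -0.48
  - -0.05
  - -0.12
  - -0.48
  - 0.05
  - -0.12
  - -0.48
  - -0.05
  - 0.12
  - -0.48
  - 0.05
  - 0.12
  - -0.48
  - -0.05
  - -0.12
  - -0.48
  - 0.05
  - -0.12
  - -0.48
  - -0.05
  k: 300000.0
  expn: 1.5
  cdamp: 1.0
  mu: 1.2
  vs: 0.02
  eps: 0.0001
  offset: 0.0
muscles:
  name:
  - hip_ext_r
  - hip_flex_r
  - hip_ext_l
  - hip_flex_l
  fmax:
  - 1500.0
  - 1500.0
  - 1500.0
  - 1500.0
  lmopt:
  - 0.1
  - 0.1
  - 0.1
  - 0.1
  ltslack:
  - 0.15
  - 0.15
  - 0.15
  - 0.15
  vmax:
  - 10.0
  - 10.0
  - 10.0
  - 10.0
  tact:
  - 0.01
  - 0.01
  - 0.01
  - 0.01
  tdeact:
  - 0.04
  - 0.04
  - 0.04
  - 0.04
  w:
  - 150.0
  - 150.0
  - 150.0
  - 150.0
  kt:
  - 12.0
  - 12.0
  - 12.0
  - 12.0
  rigid:
  - 0
  - 0
  - 0
  - 0
  poly:
  - coef:
    - 0.25
    - 0.05
    - 0.005
    expo:
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 1
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 2
    - 0
    - 0
    - 0
    - 0
    nterm: 3
  - coef:
    - 0.25
    - -0.05
    - -0.005
    expo:
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 1
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 2
    - 0
    - 0
    - 0
    - 0
    nterm: 3
  - coef:
    - 0.25
    - 0.05
    - 0.005
    expo:
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 1
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 2
    - 0
    nterm: 3
  - coef:
    - 0.25
    - -0.05
    - -0.005
    expo:
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 1
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 0
    - 2
    - 0
    nterm: 3
tor:
- 7
- 8
- 9
- 10
- 11
- 12
tor_gain:
- 300.0
- 300.0
- 300.0
- 300.0
- 300.0
- 300.0
passive:
  qlo:
  - -.inf
  - -.inf
  - -.inf
  - -6.2831853
  - -6.2831853
  - -6.2831853
  - -2.1816616
  - -0.6981317
  - -2.268928
  - -2.1816616
  - -0.6981317
  - -2.268928
  qhi:
  - .inf
  - .inf
  - .inf
  - 6.2831853
  - 6.2831853
  - 6.2831853
  - 2.1816616
  - 1.7453293
  - 0.2617994
  - 2.1816616
  - 1.7453293
  - 0.2617994
  k:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  b:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 12.0
  - 12.0
  - 12.0
  - 12.0
  - 12.0
  - 12.0
  d:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
ranges:
- -3.0
- 3.0
- 0.3
- 1.6
- -3.0
- 3.0
- -6.2831853
- 6.2831853
- -3.1415927
- 3.1415927
- -3.1415927
- 3.1415927
- -2.3561945
- 2.3561945
- -0.8726646
- 1.9198622
- -2.443461
- 0.4363323
- -2.3561945
- 2.3561945
- -0.8726646
- 1.9198622
- -2.443461
- 0.4363323
gravity:
- 0.0
- -9.81
- 0.0
body_mass: 76.0
body_height: 1.75
units:
  length: m
  angle: rad
  mass: kg
  force: 'N'
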