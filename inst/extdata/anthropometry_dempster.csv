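# 13-segment anthropometric coefficients (Dempster, as tabulated by Winter).
# mass_fraction: fraction of total body mass; com_fraction: segment CoM
# position along the proximal->distal endpoint axis. Forearm includes hand.
# Roles refer to marker-schema roles; L/R prefixes identify sides.
segment,proximal_role,distal_role,mass_fraction,com_fraction
pelvis,LHIP,RHIP,0.142,0.5
trunk,NECK,SACR,0.355,0.5
head,NECK,HEAD,0.081,0.5
thigh_L,LHIP,LKNEE,0.100,0.433
thigh_R,RHIP,RKNEE,0.100,0.433
shank_L,LKNEE,LANK,0.0465,0.433
shank_R,RKNEE,RANK,0.0465,0.433
foot_L,LANK,LTOE,0.0145,0.5
foot_R,RANK,RTOE,0.0145,0.5
upper_arm_L,LSHO,LELB,0.028,0.436
upper_arm_R,RSHO,RELB,0.028,0.436
forearm_L,LELB,LWRI,0.022,0.682
forearm_R,RELB,RWRI,0.022,0.682
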