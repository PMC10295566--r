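method,side,joint,dtw,pe
KF1+FDF,far,knee,5.08,36.11
KF1+FDF,far,hip,4.85,45.00
KF1+FDF,near,knee,2.91,18.27
KF1+FDF,near,hip,2.48,27.15
KF2+FDF,far,knee,4.17,25.81
KF2+FDF,far,hip,3.46,32.88
KF2+FDF,near,knee,2.94,17.33
KF2+FDF,near,hip,2.43,25.57
original,far,knee,4.59,25.93
original,far,hip,4.05,37.71
original,near,knee,2.95,17.90
original,near,hip,2.98,27.77
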