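approach,oacc_percent,n_bands
3D-2D CNN,80,128
3D-2D-CNN + SVM,75,128
SVM (128-band),76,128
2D CNN,72,128
1D CNN,78,128
ANN (826-band),96.7,826
RF (826-band),99.46,826
Spectral Unmixing,76,128
Proposed SVM,60,25
Proposed RF,53,25
Proposed 3DCNN,49,25
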