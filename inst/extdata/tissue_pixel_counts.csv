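patient,healthy,tumor,venous,arterial,dura
ID18,648,1587,79,14,369
ID25,801,206,90,15,94
ID29,3752,64,98,11,1599
ID30,2587,2737,487,381,1366
ID33,6671,973,842,35,1443
ID34,1186,1464,181,176,780
ID35,3864,1389,837,58,586
ID38,1740,487,113,191,825
ID47C1,174,160,58,54,567
ID47C2,715,182,14,148,129
ID50,410,1282,712,47,628
ID51,3888,2731,95,85,525
ID56,1920,1967,75,37,5922
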