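species,metal,mean_bcf
Anabasis aphylla,Cr,7.303
Alhagi camelorum,Cr,1.78
Reaumuria songonica,Cr,2.60
Haloxylon ammodendron,Cr,1.45
Anabasis aphylla,Hg,1.35
Alhagi camelorum,Hg,1.46
Reaumuria songonica,Hg,1.26
Haloxylon ammodendron,Hg,0.82
Anabasis aphylla,Cd,1.424
Alhagi camelorum,Cd,0.71
Reaumuria songonica,Cd,0.71
Haloxylon ammodendron,Cd,0.84
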