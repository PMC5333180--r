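expert,ensemble1,ensemble2,ensemble3,ensemble4,ensemble5,ensemble6,ensemble7
expert01,-1,-1,-1,-1,-1,-1,2
expert02,2,2,0,2,-2,-2,2
expert03,0,0,0,0,0,0,0
expert04,-1,-1,-1,-1,-1,-1,0
expert05,1,2,-1,-1,-1,1,1
expert06,2,2,-1,1,-1,1,2
expert07,-1,2,-1,1,1,1,1
expert08,1,1,0,0,1,1,1
expert09,1,1,1,1,1,-1,-1
expert10,2,-2,-1,2,-1,1,-2
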