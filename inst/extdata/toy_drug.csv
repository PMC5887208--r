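case_id,drug,role,route
C01,D1,suspect,oral
C02,D1,suspect,oral
C03,D1,suspect,oral
C04,D1,suspect,oral
C06,D2,suspect,oral
C07,D2,suspect,oral
C08,D2,suspect,oral
C09,D2,suspect,oral
C11,D3,suspect,oral
C12,D3,suspect,oral
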