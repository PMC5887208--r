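case_id,event
C01,E1
C02,E1
C03,E1
C04,E1
C05,E1
C06,E2
C07,E2
C08,E2
C09,E2
C10,E2
C11,E3
C12,E4
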