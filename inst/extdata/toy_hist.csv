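case_id,hist
C01,kidney injury
C02,kidney injury
C03,kidney injury
C04,kidney injury
C05,kidney injury
C06,kidney injury
C07,kidney injury
C08,kidney injury
C09,kidney injury
C10,kidney injury
C11,kidney injury
C12,kidney injury
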