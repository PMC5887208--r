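case_id,sex,age
C01,female,61
C02,male,58
C03,female,49
C04,male,72
C05,female,66
C06,male,54
C07,female,70
C08,male,45
C09,female,63
C10,male,59
C11,female,51
C12,male,68
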