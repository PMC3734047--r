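strain	abundance_12c	abundance_13c
H16	1.13	2.22
H16_dcbbLS_c	1.10	1.81
H16_dcbbLS_p	1.13	2.11
H16_ddcbbLS	1.11	1.25
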