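band,f_lo_hz,f_hi_hz,background_db_spl,measured_db_spl,difference_db_spl
Total,4,100000,85.96,112.11,26.15
Human audible,20,20000,85.91,112.03,26.12
Mouse peak,10000,20000,43.83,97.71,53.88
Ultrasonic,20000,100000,40.63,89.97,49.34
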