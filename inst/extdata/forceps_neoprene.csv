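band,f_lo_hz,f_hi_hz,background_db_spl,measured_db_spl,difference_db_spl,reduction_db_spl
Total,4,100000,88.67,100.34,11.67,14.48
Human audible,20,20000,87.87,100.36,12.49,13.63
Mouse peak,10000,20000,45.24,62.26,17.02,36.86
Ultrasonic,20000,100000,41.23,54.5,13.27,36.07
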