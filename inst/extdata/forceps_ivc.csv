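band,f_lo_hz,f_hi_hz,background_db_spl,measured_db_spl,difference_db_spl
Total,4,100000,65.4,102.3,36.9
Human audible,20,20000,79.7,104.1,24.4
Mouse peak,10000,20000,36,83.4,47.4
Ultrasonic,20000,100000,40.2,76.4,36.2
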