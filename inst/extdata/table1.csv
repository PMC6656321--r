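animal_id,year,mass_kg,total_length_cm,treatments,accelerometer
SB02,2016,7.30,109,24;28;32,FALSE
SB03,2016,2.66,80,24;28;32,FALSE
SB04,2016,5.09,99,24;28;32,FALSE
SB05,2016,5.46,98,24;28;32,FALSE
SB12,2016,5.69,103.5,24;28;32,FALSE
SB28,2017,7.76,113.5,24;28;32,TRUE
SB29,2017,3.31,91,24;28;32,TRUE
SB30,2017,4.22,94,24;28;32,TRUE
SB31,2017,3.98,91,24;28;32,TRUE
SB32,2017,2.56,81,24;28,TRUE
SB33,2017,6.81,109,24;28;32,TRUE
SB34,2017,6.84,107,24;28;32,TRUE
SB37,2017,2.60,79.5,32,TRUE
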