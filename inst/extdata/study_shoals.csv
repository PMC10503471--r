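"shoal_id","stage","treatment_temp_c","recorded_temp","body_length_mm","n_fish"
"L1","larva",32,"32.0 ± 0.7",8,5
"L2","larva",28,"28.1 ± 0.2",8.4,5
"L3","larva",32,"32.1 ± 0.2",8,5
"L4","larva",28,"28.0 ± 0.2",8.4,5
"L5","larva",32,"32.0 ± 0.6",8,5
"L6","larva",28,"28.1 ± 0.1",8.4,5
"L7","larva",32,"32.0 ± 0.3",8,5
"L8","larva",28,"28.1 ± 0.2",8.4,5
"L9","larva",32,"32.1 ± 0.2",8,5
"L10","larva",28,"28.0 ± 0.2",8.4,5
"J1","juvenile",32,"32.2 ± 0.4",13.45,5
"J2","juvenile",28,"28.1 ± 0.1",14.32,5
"J3","juvenile",32,"32.1 ± 0.2",13.45,5
"J4","juvenile",28,"27.9 ± 0.4",14.32,5
"J5","juvenile",32,"31.9 ± 0.2",13.45,5
"J6","juvenile",28,"28.1 ± 0.1",14.32,5
"J7","juvenile",32,"32.2 ± 0.1",13.45,5
"J8","juvenile",28,"28.1 ± 0.0",14.32,5
"J9","juvenile",32,"–",NA,5
"J10","juvenile",28,"27.9 ± 0.4",14.32,5
"A1","adult",32,"31.9 ± 0.5",36.04,5
"A2","adult",28,"28.0 ± 0.2",36.84,5
"A3","adult",32,"32.2 ± 0.2",36.04,5
"A4","adult",28,"28.1 ± 0.3",36.84,5
"A5","adult",32,"31.9 ± 0.4",36.04,5
"A6","adult",28,"28.1 ± 0.1",36.84,5
"A7","adult",32,"31.8 ± 0.3",36.04,5
"A8","adult",28,"28.1 ± 0.2",36.84,5
"A9","adult",32,"32.2 ± 0.2",36.04,5
"A10","adult",28,"28.0 ± 0.2",36.84,5
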