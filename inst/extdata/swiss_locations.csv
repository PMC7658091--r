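name,lat,lon,altitude,ei_reference,ei_a2_2070_2099,generations_reference,generations_a2_2070_2099,growth_weeks_reference,growth_weeks_a2_2070_2099
Zurich,47.38,8.52,408,7,23,1.35,2.49,26,33
St. Gallen,47.43,9.39,674,0,9,0.91,1.95,25,32
Chur,46.85,9.52,593,14,20,1.32,2.52,26,35
Lugano,46.02,8.95,275,15,23,1.83,3.24,31,39
Sion,46.23,7.35,515,5,4,1.63,2.99,26,32
Lausanne,46.54,6.58,495,14,22,1.53,2.79,30,36
Delemont,47.37,7.34,435,12,19,1.35,2.46,27,32
Basel,47.55,7.57,260,16,18,1.55,2.73,29,36
Aarau,47.39,8.05,384,12,20,1.35,2.48,27,33
Bern,46.95,7.44,542,10,18,1.14,2.21,25,31
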