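nutrient_id,lower,upper,basis,energy_per_g
protein,10,20,percent_energy,17
fat,25,40,percent_energy,37
carbohydrate,45,60,percent_energy,17
fiber,25,NA,absolute,NA
iron,9,60,absolute,NA
zinc,7,25,absolute,NA
vitamin_b12,2,NA,absolute,NA
sodium,NA,2400,absolute,NA
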