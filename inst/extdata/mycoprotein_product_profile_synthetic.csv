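nutrient,per_100g
energy_kj,450
protein,14
fat,7
carbohydrate,6
fiber,4.5
iron,0.4
zinc,5
vitamin_b12,0.1
sodium,350
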