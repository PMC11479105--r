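code,name,unit,trace_threshold
energy_kcal,Energy,kcal,
energy_kj,Energy,kJ,
water,Water,g,
protein,Total protein,g,
fat,Total fat,g,
carb_avail,Available carbohydrates,g,
fiber,Total dietary fiber,g,
sugar,Soluble carbohydrates,g,
starch,Starch,g,
ash,Ash,g,
alcohol,Alcohol,g,
sodium,Sodium,mg,
chloride,Chloride,mg,
potassium,Potassium,mg,
retinol,Retinol,ug,0.6
vitamin_d,Vitamin D,ug,0.06
alpha_tocopherol,Alpha-tocopherol,mg,0.006
vitamin_b12,Vitamin B12,ug,0.06
sfa_short,Short-chain saturated fatty acids,g,
pufa_other,Other polyunsaturated fatty acids,g,
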