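category,scenario,unit,con_value,dfm_value
climate_change,BT-2017,kg CO2 eq,42177.46,41291.90
climate_change,NRC-2012,kg CO2 eq,45217.37,44578.41
climate_change,AGPIC-2021,kg CO2 eq,45587.53,44858.20
climate_change_land_use,BT-2017,kg CO2 eq,6127.30,5360.84
climate_change_land_use,NRC-2012,kg CO2 eq,6247.52,5886.02
climate_change_land_use,AGPIC-2021,kg CO2 eq,6309.91,5929.40
climate_change_fossil,BT-2017,kg CO2 eq,9523.82,9228.02
climate_change_fossil,NRC-2012,kg CO2 eq,9955.88,9775.80
climate_change_fossil,AGPIC-2021,kg CO2 eq,10140.58,9920.43
eutrophication_freshwater,BT-2017,kg P eq,1.77,1.66
eutrophication_freshwater,NRC-2012,kg P eq,1.99,1.89
eutrophication_freshwater,AGPIC-2021,kg P eq,1.87,1.76
eutrophication_marine,BT-2017,kg N eq,0.76,0.74
eutrophication_marine,NRC-2012,kg N eq,0.80,0.78
eutrophication_marine,AGPIC-2021,kg N eq,0.77,0.75
ecotoxicity_freshwater,BT-2017,CTUe,1522679.95,1489873.47
ecotoxicity_freshwater,NRC-2012,CTUe,1579670.56,1554892.25
ecotoxicity_freshwater,AGPIC-2021,CTUe,1559309.71,1530789.17
resource_minerals,BT-2017,kg Sb eq,0.42,0.39
resource_minerals,NRC-2012,kg Sb eq,0.46,0.44
resource_minerals,AGPIC-2021,kg Sb eq,0.44,0.42
resource_fossils,BT-2017,MJ,764.16,727.86
resource_fossils,NRC-2012,MJ,779.25,762.64
resource_fossils,AGPIC-2021,MJ,789.08,769.13
water_use,BT-2017,m3 depriv.,7123.41,6917.37
water_use,NRC-2012,m3 depriv.,7207.35,7026.36
water_use,AGPIC-2021,m3 depriv.,6921.79,6692.66
land_use,BT-2017,Pt,1.26,1.22
land_use,NRC-2012,Pt,1.36,1.33
land_use,AGPIC-2021,Pt,1.31,1.27
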