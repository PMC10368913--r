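service,group,agriculture,forest,settlement,water
food production,provisioning,54,43,0,41
raw material,provisioning,0,138,0,0
gas regulation,regulating,0,0,0,0
climate regulation,regulating,0,141,0,0
disturbance regulation,regulating,0,2,0,0
water regulation,regulating,0,2,0,5445
water supply,regulating,0,3,0,2117
waste treatment,regulating,0,87,0,665
soil formation and retention,supporting,0,10,0,0
nutrient cycling,supporting,0,361,0,0
erosion control,supporting,0,96,0,0
pollination,supporting,14,0,0,0
biodiversity,supporting,24,2,0,0
genetic resources,supporting,0,16,0,0
recreation and tourism,cultural,0,68,0,230
cultural,cultural,0,2,0,0
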