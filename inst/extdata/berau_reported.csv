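name,value,units
gross_total,9.73,TgCO2/yr
gross_ci95,1.95,TgCO2/yr
seq_total,0.82,TgCO2/yr
seq_ci95,0.41,TgCO2/yr
net_total,8.91,TgCO2/yr
net_ci95,1.99,TgCO2/yr
forest_loss_gross,8.13,TgCO2/yr
forest_loss_ci95,1.78,TgCO2/yr
biomass_loss_gross,8.67,TgCO2/yr
regrowth_seq,0.71,TgCO2/yr
logging_gross,1.60,TgCO2/yr
logging_ci95,0.77,TgCO2/yr
logging_felling,0.97,TgCO2/yr
logging_skidding,0.35,TgCO2/yr
logging_haul,0.28,TgCO2/yr
logging_products,0.11,TgCO2/yr
logging_regrowth_seq,0.11,TgCO2/yr
stock_2000_tgc,427,TgC
asl_ha_yr,9344,ha/yr
harvest_m3_yr,297766,m3/yr
overall_uncertainty_pct,29,percent
loss_trend_r2,0.141,unitless
loss_trend_f,1.310,unitless
loss_trend_p,0.285,unitless
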