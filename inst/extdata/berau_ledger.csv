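zone,permit,type,landArea,forestArea,areaDisturbed,regrowth,gross,seq,net,percentPrinted
APL,HGU,Oil Palm,206683,194513,4509,1379,2.38,0.130,2.25,25.3
APL,None,Oil Palm,NA,NA,477,74,0.27,0.007,0.26,2.9
APL,None,Agriculture / Other,NA,NA,3786,1306,2.79,0.313,2.48,27.8
APL,HGU,Agriculture / Other,206683,194513,1050,328,0.56,0.031,0.53,5.9
APL,PKP2B,Mining,117745,102312,351,79,0.18,0.007,0.17,2.0
APL,None,Mining,NA,NA,111,15,0.05,0.001,0.05,0.6
HP/HPT,HA,Skidding/Felling,898725,888438,8654,8654,1.32,0.076,1.25,14.0
HP/HPT,HA,Logging Roads,898725,888438,690,259,0.28,0.024,0.25,2.8
HP/HPT,HTI,Fiber Plantation,266351,242322,2025,2029,1.02,0.191,0.82,9.2
HP/HPT,HA,Agriculture / Other,898725,888438,1380,314,0.79,0.030,0.77,8.6
HP/HPT,HTI,Mining,266351,242322,104,20,0.06,0.002,0.06,0.7
HL,None,Agriculture / Other,NA,NA,65,49,0.04,0.00,0.03,0.4
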