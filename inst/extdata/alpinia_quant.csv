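chemical,c_ref,logie_pred_before,c_pred_before,logie_pred_after,c_pred_after
pinocembrin,15,0.28,34,-0.99,37
(-)-epicatechin,23,-0.60,78,-1.55,41
kaempferol,NA,1.04,1.2,-0.29,2.4
galangin,110,1.25,66,0.06,146
"luteolin-3',7-diglucoside",0.16,-0.51,13,-0.36,6
catechin,1.2,0.49,1.1,-0.07,1.2
pinobanksin,NA,0.63,33,-0.46,45
kaempferide,NA,1.10,24,-0.56,51
galangin 7-glucoside,NA,0.83,7.8,0.10,11
galangin 3-rhamnoside,NA,-0.06,2.2,-0.23,1.6
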