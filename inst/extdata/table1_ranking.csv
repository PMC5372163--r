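accession,gene,p_value,fold_change,d_eucl_printed,more_abundant_in
P22676,CALB2,0.0004,22.4,3.64,epithelioid
O43790,KRT86,0.0148,110.5,2.74,epithelioid
P08727,KRT19,0.0047,24.2,2.71,epithelioid
P13647,KRT5,0.0232,15.7,2.03,epithelioid
P05787,KRT8,0.0484,6.9,1.56,epithelioid
P51970,NDUFA8,0.0012,4.9,2.99,epithelioid
P22735,TGM1,0.0015,6.7,2.93,epithelioid
Q9Y4L1,HYOU1,0.0120,3.8,2.01,epithelioid
P12109,COL6A1,0.0238,4.2,1.74,sarcomatoid
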