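year,price_usd_per_l,volume_mn_l,fiscal_revenue_mm_usd
2016,0.67,3782,NA
2017,0.6916667,3819.4444,45066
2018,0.7166667,3857.8605,46869
2019,0.7333333,3896.2766,48744
2020,0.75,3936.1702,50693
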