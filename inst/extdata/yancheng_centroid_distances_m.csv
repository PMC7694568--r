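year,phragmites,suaeda,mudflat
1995,5079.82,7949.92,13243.89
2000,5268.48,8328.99,13451.33
2005,5424.88,8665.32,13644.77
2010,5641.46,8919.29,13819.33
2015,5867.64,9141.70,13977.54
2017,5957.32,9231.02,14041.36
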