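class,y1985,y1990,y1995,y2000,y2005,y2010,y2015,y2017
suaeda,3773.05,4584.83,4771.35,5227.79,3385.65,2656.16,1498.06,992.46
phragmites,5038.48,4887.95,4765.92,3221.19,4904.90,5602.39,8242.41,8751.37
spartina,214.53,211.52,680.60,2173.89,3381.34,4318.84,3985.08,3925.46
mudflat,14424.51,13592.65,13232.36,10213.61,8640.78,8140.35,8417.34,8295.04
water,318.86,492.74,328.18,545.36,813.28,445.59,504.19,472.38
pond,0,0,0,2018.31,2209.76,2261.26,252.81,342.92
road,61.00,60.82,52.07,430.31,494.83,405.87,930.70,1050.98
total,23830.43,23830.51,23830.47,23830.46,23830.54,23830.46,23830.60,23830.60
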