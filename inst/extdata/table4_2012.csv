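region,year,passenger_flights,cargo_flights,ships
Singapore,2012,10812,251,1410
New Zealand—North Island,2012,15546,426,537
Hong Kong,2012,5296,177,342
New Zealand—South Island,2012,4762,261,110
China—Shanghai,2012,1557,104,390
Papua New Guinea—National Capital District,2012,2193,183,157
Malaysia—Selangor,2012,4317,127,105
Taiwan (Province of China),2012,634,0,613
China—Guangdong,2012,1624,0,278
Japan—Tiba,2012,1415,0,237
Republic of Korea—Incheon Gwang'yeogsi,2012,1105,105,62
New Caledonia,2012,587,0,229
Indonesia—Bali,2012,6600,0,42
China—Shandong,2012,0,0,737
China—Fujian,2012,0,105,136
China—Jiangsu,2012,0,0,597
Republic of Korea—Jeonranamdo,2012,0,0,486
United States—California,2012,3106,0,46
Indonesia—Banten,2012,881,0,111
United States—Hawaii,2012,933,104,3
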