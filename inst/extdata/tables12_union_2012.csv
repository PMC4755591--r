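region,year,passenger_flights,cargo_flights,ships
New Zealand—North Island,2012,15546,426,537
Singapore,2012,10812,251,1410
Indonesia—Bali,2012,6600,0,42
Hong Kong,2012,5296,177,342
New Zealand—South Island,2012,4762,261,110
Malaysia—Selangor,2012,4317,127,105
United States—California,2012,3106,0,46
Thailand—Samut Prakan,2012,2821,17,3
Fiji—Western,2012,2608,0,5
Papua New Guinea—National Capital District,2012,2193,183,157
China—Shandong,2012,0,0,737
Taiwan (Province of China),2012,634,0,613
China—Jiangsu,2012,0,0,597
Republic of Korea—Jeonranamdo,2012,0,0,486
China—Shanghai,2012,1557,104,390
China—Guangdong,2012,1624,0,278
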