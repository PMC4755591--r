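region,year,passenger_flights,cargo_flights,ships
Singapore,2012,10812,251,1410
New Zealand—North Island,2012,15546,426,537
China—Shandong,2012,,,737
Taiwan (Province of China),2012,634,,613
China—Jiangsu,2012,,,597
Hong Kong,2012,5296,177,342
Republic of Korea—Jeonranamdo,2012,,,486
China—Shanghai,2012,1557,104,390
China—Guangdong,2012,1624,,278
New Zealand—South Island,2012,4762,261,110
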