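country,iso3,year,p5,p95
Dem Rep of the Congo,COD,2000,28.5,75.3
Dem Rep of the Congo,COD,2019,1.5,17.5
Ethiopia,ETH,2000,39.6,87.5
Ethiopia,ETH,2019,1.6,32.4
India,IND,2000,7.2,59.7
India,IND,2019,1.6,21.3
Bangladesh,BGD,2000,3.3,17.7
Burundi,BDI,2000,10.2,27.3
Burundi,BDI,2019,1.5,3.9
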