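country,iso3,income_group,gavi_supported,segmentation_group,learning_hub
Afghanistan,AFG,Low-income,TRUE,Conflict/fragile,FALSE
Angola,AGO,Lower-middle income,TRUE,Core-ESA (Priority),FALSE
Bangladesh,BGD,Lower-middle income,TRUE,Core-Rest of World (Priority),TRUE
Benin,BEN,Low-income,TRUE,Core-WCA (Priority),FALSE
Burkina Faso,BFA,Low-income,TRUE,Core-WCA (Priority),FALSE
Burundi,BDI,Low-income,TRUE,Core-ESA (Standard),FALSE
Cambodia,KHM,Lower-middle income,TRUE,Core-Rest of World (Standard),FALSE
Cameroon,CMR,Lower-middle income,TRUE,Core-WCA (Priority),FALSE
Central African Rep,CAF,Low-income,TRUE,Conflict/fragile,FALSE
Chad,TCD,Low-income,TRUE,Conflict/fragile,FALSE
Comoros,COM,Lower-middle income,TRUE,Core-ESA (Standard),FALSE
Congo,COG,Lower-middle income,TRUE,Core-WCA (Priority),FALSE
Cote d'Ivoire,CIV,Lower-middle income,TRUE,Core-WCA (Priority),FALSE
Dem Rep of the Congo,COD,Low-income,TRUE,High impact,FALSE
Djibouti,DJI,Lower-middle income,TRUE,Core-ESA (Priority),FALSE
Eritrea,ERI,Low-income,TRUE,Core-ESA (Standard),FALSE
Ethiopia,ETH,Low-income,TRUE,High impact,FALSE
Gambia,GMB,Low-income,TRUE,Core-WCA (Standard),FALSE
Ghana,GHA,Lower-middle income,TRUE,Core-WCA (Priority),FALSE
Guinea,GIN,Low-income,TRUE,Core-WCA (Priority),FALSE
Guinea-Bissau,GNB,Low-income,TRUE,Core-WCA (Priority),FALSE
Haiti,HTI,Low-income,TRUE,Conflict/fragile,FALSE
India,IND,Lower-middle income,TRUE,High impact,FALSE
Kenya,KEN,Lower-middle income,TRUE,Core-ESA (Priority),FALSE
Kyrgyzstan,KGZ,Lower-middle income,TRUE,Core-Rest of World (Standard),FALSE
Laos,LAO,Lower-middle income,TRUE,Core-Rest of World (Priority),FALSE
Lesotho,LSO,Lower-middle income,TRUE,Core-ESA (Standard),FALSE
Liberia,LBR,Low-income,TRUE,Core-WCA (Standard),FALSE
Madagascar,MDG,Low-income,TRUE,Core-ESA (Priority),FALSE
Malawi,MWI,Low-income,TRUE,Core-ESA (Priority),FALSE
Mali,MLI,Low-income,TRUE,Conflict/fragile,TRUE
Mauritania,MRT,Lower-middle income,TRUE,Core-WCA (Standard),FALSE
Mozambique,MOZ,Low-income,TRUE,Core-ESA (Priority),FALSE
Myanmar,MMR,Lower-middle income,TRUE,Core-Rest of World (Priority),FALSE
Nepal,NPL,Low-income,TRUE,Core-Rest of World (Priority),FALSE
Niger,NER,Low-income,TRUE,Conflict/fragile,FALSE
Nigeria,NGA,Lower-middle income,TRUE,High impact,TRUE
Pakistan,PAK,Lower-middle income,TRUE,High impact,FALSE
Papua New Guinea,PNG,Lower-middle income,TRUE,Conflict/fragile,FALSE
Rwanda,RWA,Low-income,TRUE,Core-ESA (Standard),FALSE
Sao Tome and Principe,STP,Lower-middle income,TRUE,Core-WCA (Standard),FALSE
Senegal,SEN,Lower-middle income,TRUE,Core-WCA (Standard),FALSE
Sierra Leone,SLE,Low-income,TRUE,Core-WCA (Standard),FALSE
Somalia,SOM,Low-income,TRUE,Conflict/fragile,FALSE
South Sudan,SSD,Low-income,TRUE,Conflict/fragile,FALSE
Sudan,SDN,Lower-middle income,TRUE,Conflict/fragile,FALSE
Tajikistan,TJK,Low-income,TRUE,Core-Rest of World (Standard),FALSE
Tanzania,TZA,Low-income,TRUE,Core-ESA (Priority),FALSE
Timor-Leste,TLS,Lower-middle income,TRUE,Core-Rest of World (Standard),FALSE
Togo,TGO,Low-income,TRUE,Core-WCA (Priority),FALSE
Uganda,UGA,Low-income,TRUE,Core-ESA (Priority),TRUE
Uzbekistan,UZB,Lower-middle income,TRUE,Core-Rest of World (Standard),FALSE
Vietnam,VNM,Lower-middle income,TRUE,Core-Rest of World (Standard),FALSE
Yemen,YEM,Low-income,TRUE,Conflict/fragile,FALSE
Zambia,ZMB,Lower-middle income,TRUE,Core-ESA (Priority),FALSE
Zimbabwe,ZWE,Lower-middle income,TRUE,Core-ESA (Standard),FALSE
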