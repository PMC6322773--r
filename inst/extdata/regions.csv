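country,region
Ethiopia,Africa
Kenya,Africa
Niger,Africa
Malawi,Africa
Democratic Republic of the Congo,Africa
Chad,Africa
South Sudan,Africa
Mali,Africa
Burkina Faso,Africa
Somalia,Africa
Bangladesh,South-East Asia
India,South-East Asia
Nepal,South-East Asia
Myanmar,South-East Asia
Indonesia,South-East Asia
Timor-Leste,South-East Asia
Yemen,Middle East
Afghanistan,Middle East
Iraq,Middle East
Syria,Middle East
Pakistan,Middle East
Haiti,Americas
Guatemala,Americas
Honduras,Americas
Bolivia,Americas
Tajikistan,Eastern Europe
Kyrgyzstan,Eastern Europe
Uzbekistan,Eastern Europe
Albania,Eastern Europe
Philippines,Western Pacific
Cambodia,Western Pacific
Laos,Western Pacific
Papua New Guinea,Western Pacific
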