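region,quantity,year,value
World,u5mr,1990,93.5
World,u5mr,2000,76.7
World,u5mr,2015,42.9
World,u5mr,2024,37.4
World,nmr,1990,36.6
World,nmr,2000,30.3
World,nmr,2015,19.4
World,nmr,2024,17.2
World,imr,2024,27.7
Eastern Europe and Central Asia,u5mr,1990,46.5
Eastern Europe and Central Asia,u5mr,2024,11.1
North America,u5mr,1990,11.0
North America,u5mr,2024,6.4
West and Central Africa,u5_deaths_thousands,2024,1918
Eastern and Southern Africa,u5_deaths_thousands,2024,1014
South Asia,u5_deaths_thousands,2024,1196
World,u5_deaths_thousands,2024,4858
World,neonatal_deaths_thousands,2024,2271
Sub-Saharan Africa,births_millions,2024,42.4
World,births_millions,2024,132.4
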