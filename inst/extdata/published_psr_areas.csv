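variable,class,calibrachoa,petunia
Altitude,A,0.08,0.04
Annual Mean Temperature,T,0.01,-0.10
Mean Diurnal Range,T,-0.05,-0.16
Isothermality,T,0.09,0.00
Temperature Seasonality,T,-0.04,-0.07
Max Temperature of Warmest Month,T,-0.01,-0.08
Min Temperature of Coldest Month,T,0.10,-0.11
Temperature Annual Range,T,-0.13,-0.15
Mean Temperature of Wettest Quarter,T,-0.22,-0.32
Mean Temperature of Driest Quarter,T,0.04,-0.10
Mean Temperature of Warmest Quarter,T,0.02,-0.05
Mean Temperature of Coldest Quarter,T,-0.03,-0.17
Annual Precipitation,P,-0.20,-0.13
Precipitation of Wettest Month,P,-0.08,-0.07
Precipitation of Driest Month,P,-0.21,-0.23
Precipitation Seasonality,P,-0.14,-0.39
Precipitation of Wettest Quarter,P,-0.11,-0.07
Precipitation of Driest Quarter,P,-0.25,-0.23
Precipitation of Warmest Quarter,P,0.03,-0.01
Precipitation of Coldest Quarter,P,-0.20,-0.26
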