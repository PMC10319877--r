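school,latitude,longitude,district
OAK,41.401000,2.122000,Sarria
VER,41.388000,2.186000,Ciutat Vella
VIR,41.419000,2.162000,Horta-Guinardo
SAN,41.435000,2.189000,Sant Andreu
IPC,41.395000,2.170000,Eixample
BEL,41.349000,2.110000,Hospitalet
MON,41.367000,2.144000,Sants-Montjuic
ZAF,41.413000,2.187000,Sant Marti
IFT,41.425000,2.168000,Horta-Guinardo
SGV,41.315000,2.019000,Viladecans
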