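token,field,value
WALK,mode,walk
WALKING,mode,walk
PEU,mode,walk
APEU,mode,walk
CAMINANT,mode,walk
ANDANDO,mode,walk
BUS,mode,bus
AUTOBUS,mode,bus
CAR,mode,car
COTXE,mode,car
COCHE,mode,car
SCOOTER,mode,scooter
PATINET,mode,scooter
PATINETE,mode,scooter
BIKE,mode,bike
BICYCLE,mode,bike
BICI,mode,bike
BICICLETA,mode,bike
METRO,mode,metro
SUBWAY,mode,metro
TRAIN,mode,train
TREN,mode,train
ALONE,companionship,alone
SOL,companionship,alone
SOLA,companionship,alone
ACCOMPANIED,companionship,accompanied
GROUP,companionship,accompanied
FRIENDS,companionship,accompanied
ACOMPANYAT,companionship,accompanied
ACOMPANYADA,companionship,accompanied
AMICS,companionship,accompanied
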