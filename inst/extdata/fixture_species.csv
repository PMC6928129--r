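name,class,y_init,y_max,tau_override
TGFb,signaling,0,1,
IL1b,signaling,0,1,
IL6,signaling,0,1,
TNFa,signaling,0,1,
AngII,signaling,0,1,
Mech,signaling,0,1,
TGFbR1,signaling,0,1,
IL1bR,signaling,0,1,
TNFaR,signaling,0,1,
gp130,signaling,0,1,
STAT,signaling,0,1,
ET1,translation,0,1,
ET1R,signaling,0,1,
ERK,signaling,0,1,
p38,signaling,0,1,
NFKB,signaling,0,1,
AP1,signaling,0,1,
Smad3,signaling,0,1,
Smad7,signaling,0,1,
ColImRNA,transcription,0,1,
ColIIImRNA,transcription,0,1,
aSMA,transcription,0,1,
Factin,translation,0,1,
MMP1,transcription,0,1,
latentTGFb_net,transcription,0,1,
IL6_net,transcription,0,1,
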