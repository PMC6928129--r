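rule,w,n,ec50
=> TGFb,0.25,,
=> IL1b,0.25,,
=> IL6,0.25,,
=> TNFa,0.25,,
=> AngII,0.25,,
=> Mech,0.25,,
TGFb & !Smad7 => TGFbR1,0.9,,
IL1b => IL1bR,0.9,,
IL6 => gp130,0.9,,
gp130 => STAT,0.9,,
TNFa => TNFaR,0.9,,
IL1bR => Smad7,0.7,,
STAT => Smad7,0.7,,
TGFbR1 => Smad3,0.9,,
STAT => Smad3,0.35,,
IL1bR => NFKB,0.8,,
TNFaR => NFKB,0.4,,
p38 => NFKB,0.6,,
STAT => NFKB,0.5,,
TGFbR1 => ERK,0.5,,
AngII => ERK,0.4,,
ET1R => ERK,0.85,,
IL1bR => p38,0.6,,
ET1R => p38,0.85,,
ERK => AP1,0.85,,
p38 => AP1,0.6,,
AP1 => ET1,0.9,,
ET1 => ET1R,0.9,,
AP1 => latentTGFb_net,0.8,,
NFKB => IL6_net,0.8,,
AP1 & !Smad3 => MMP1,0.75,,
NFKB & !Smad3 => MMP1,0.75,,
Smad3 => ColImRNA,0.6,,
Smad3 => ColIIImRNA,0.6,,
Smad3 => aSMA,0.8,,
Smad3 => Factin,0.7,,
Mech => Factin,0.4,,
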