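species,baseline,stimulated,tgfb_dose,tgfb_il1b
TGFb,0.25,0.5,0.9661835749,0.9661835749
IL1b,0.25,0.5,0.25,0.5333333333
IL6,0.25,0.5,0.25,0.25
TNFa,0.25,0.5,0.25,0.25
AngII,0.25,0.25,0.25,0.25
Mech,0.25,0.25,0.25,0.25
TGFbR1,0.1316337914,0.3019009915,0.8434545628,0.7661770279
IL1bR,0.1341228276,0.3503064631,0.1341228276,0.3828316223
TNFaR,0.1341228276,0.3503064631,0.1341228276,0.1341228276
gp130,0.1341228276,0.3503064631,0.1341228276,0.1341228276
STAT,0.0562986339,0.2142656639,0.0562986339,0.0562986339
ET1,0.0088869735,0.0384394863,0.1668791758,0.1631897244
ET1R,0.0012629398,0.0098093458,0.0763735574,0.0740283959
ERK,0.088334207,0.1518484942,0.447181462,0.4019951995
p38,0.0376071792,0.1440177427,0.0608298857,0.1809631212
NFKB,0.0882408196,0.3401191847,0.0938260237,0.2853248412
AP1,0.0358204512,0.1020629684,0.2925565676,0.2878856382
Smad3,0.0609945952,0.2090716767,0.7174516129,0.6306241301
Smad7,0.0562305611,0.2367866914,0.0562305611,0.1990157858
ColImRNA,0.0124762726,0.0697139644,0.3829973602,0.3211596748
ColIIImRNA,0.0124762726,0.0697139644,0.3829973602,0.3211596748
aSMA,0.0166350301,0.0929519525,0.510663147,0.4282128998
Factin,0.0732981324,0.1360948345,0.4798047827,0.4119613287
MMP1,0.0326602073,0.175505673,0.0600780431,0.1216750639
latentTGFb_net,0.007899532,0.0341684323,0.1483370452,0.1450575328
IL6_net,0.0278799908,0.1828245782,0.0303773621,0.1432680722
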