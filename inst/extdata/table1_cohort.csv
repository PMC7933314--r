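patient_id,maa_injections,tgv_cect_ml,tgv_cbct_ml,tgv_maa_ml,prescribed_gbq,tgv_pet_ml,lobar_or_total,changed_administration
1,I:0.75;LHA:0.25,640,626,640,I:0.75;LHA:0.25,1445,0,1
2,VI:0.5;VIII:0.5,392,,412,VI:0.5;VIII:0.2,654,0,0
3,IV:0.5;VIII:0.5,270,206,537,LHA:0.8;RHA:0.7,1561,1,1
4,IV_subsegmental:0.5;VIII_subsegmental:0.5,25,25,83,IV_subsegmental:0.3;VIII_subsegmental:0.6,405,0,1
5,IV:1,99,144,218,IV:1,257,0,0
6,V-VIII:0.5;IV:0.5,267,292,858,V-VIII:0.5;IV:1,755,0,0
7,IV:1,135,70,133,IV:1,181,0,0
8,VI-VII:1,276,228,451,VI-VII:1.5,420,0,0
9,VIII:0.5;VI:0.5,746,511,1127,VIII:1.1;VI:0.5,1277,0,0
10,V-VIII:0.5;InfPhrenic:0.5,340,480,707,V-VIII:0.65;InfPhrenic:0.65,870,0,0
11,RHA:0.5;RInfPhrenic:0.5,1147,1515,1097,RHA:0.9;RInfPhrenic:0.7,1298,0,0
12,IV:1,361,,350,IV_branch1:0.4;IV_branch2:0.4,399,0,1
13,VIII:0.33;VII:0.33;II:0.33,960,,917,VIII:0.5;VII:0.5;II:0.2,1118,0,0
14,V-VIII:0.75;IV:0.25,537,,489,V-VIII:0.3;IV:0.7,622,0,0
15,RHA:0.75;IV:0.25,1550,1860,1276,RHA:1.2;IV:0.3,1373,0,0
16,VIII:0.5;VII:0.5,510,903,1260,VIII:0.7;VII:0.7,1357,0,0
17,IV:0.75;II:0.25,290,450,254,IV:0.65;II:0.25,350,0,0
18,AccessoryHA:0.42;ProperHA:0.35;IV:0.22,1186,,1313,AccessoryHA:1.7;ProperHA:1.3;IV:0.4,1380,0,0
19,RHA:0.25;LHA:0.75,1955,1975,1468,RHA:0.4;LHA:1,1536,1,0
20,RHA:1,2260,2305,2279,RHA:3.4,2420,1,0
21,RHA:0.75;LHA:0.25,1285,1387,1516,RHA:1;LHA:0.18,1683,1,0
22,RHA:1,760,974,986,RHA:0.82,992,1,0
23,RHA:1,700,971,802,RHA:0.64,922,1,0
24,RHA:1,580,966,795,RHA:1,792,1,0
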