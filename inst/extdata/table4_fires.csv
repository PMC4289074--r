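date,area_ha,source,cluster,temp,rh,solar,soil
5/27/2006,1914,lightning,7,25,77,0.26,4.9
6/24/2000,1652,lightning,7,25,82,0.25,3.7
6/22/1998,549,lightning,7,28,75,0.30,7.1
6/12/2007,297,lightning,1,26,73,0.26,27.5
5/13/2009,269,lightning,3,23,80,0.21,4.5
3/2/1997,252,lightning,3,23,77,0.20,12.0
5/28/2006,247,lightning,7,27,69,0.29,4.8
6/6/2000,241,lightning,7,28,71,0.30,3.2
6/17/2001,226,lightning,1,26,79,0.31,19.4
5/7/1997,181,lightning,4,22,70,0.28,18.6
5/4/2006,2128,military,6,24,61,0.32,7.2
3/7/2001,1405,military,4,13,48,0.29,3.5
6/15/2000,1038,military,7,27,72,0.29,3.4
5/4/2006,748,military,6,24,61,0.32,7.2
2/12/1999,674,military,3,21,86,0.12,19.7
6/8/1998,651,military,1,26,82,0.23,9.3
12/15/2007,557,military,3,23,86,0.10,9.5
3/31/2006,547,military,5,20,70,0.28,13.3
5/4/2006,506,military,6,24,61,0.32,7.2
1/7/1997,452,military,3,21,79,0.16,11.8
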