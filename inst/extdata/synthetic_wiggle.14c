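# synthetic wiggle calibration curve (not a measured curve); CAL BP, 14C age, error
7100,7078.34936490539,15
7080,7065.30536869269,15
7060,7054.80220772956,15
7040,7045.19779227044,15
7020,7034.69463130731,15
7000,7021.65063509461,15
6980,7004.86304738421,15
6960,6983.77641290738,15
6940,6958.57862063693,15
6920,6930.1684160769,15
6900,6900,15
6880,6869.8315839231,15
6860,6841.42137936307,15
6840,6816.22358709262,15
6820,6795.13695261579,15
6800,6778.34936490539,15
6780,6765.30536869269,15
6760,6754.80220772956,15
6740,6745.19779227044,15
6720,6734.69463130731,15
6700,6721.65063509461,15
6680,6704.86304738421,15
6660,6683.77641290738,15
6640,6658.57862063693,15
6620,6630.1684160769,15
6600,6600,15
6580,6569.8315839231,15
6560,6541.42137936307,15
6540,6516.22358709262,15
6520,6495.13695261579,15
6500,6478.34936490539,15
6480,6465.30536869269,15
6460,6454.80220772956,15
6440,6445.19779227044,15
6420,6434.69463130731,15
6400,6421.65063509461,15
6380,6404.86304738421,15
6360,6383.77641290738,15
6340,6358.57862063693,15
6320,6330.1684160769,15
6300,6300,15
6280,6269.83158392311,15
6260,6241.42137936307,15
6240,6216.22358709262,15
6220,6195.13695261579,15
6200,6178.34936490539,15
6180,6165.30536869269,15
6160,6154.80220772956,15
6140,6145.19779227044,15
6120,6134.69463130731,15
6100,6121.65063509461,15
6080,6104.86304738421,15
6060,6083.77641290738,15
6040,6058.57862063693,15
6020,6030.16841607689,15
6000,6000,15
5980,5969.8315839231,15
5960,5941.42137936307,15
5940,5916.22358709262,15
5920,5895.13695261579,15
5900,5878.34936490539,15
5880,5865.30536869269,15
5860,5854.80220772956,15
5840,5845.19779227044,15
5820,5834.69463130731,15
5800,5821.65063509461,15
5780,5804.86304738421,15
5760,5783.77641290738,15
5740,5758.57862063693,15
5720,5730.1684160769,15
5700,5700,15
5680,5669.8315839231,15
5660,5641.42137936307,15
5640,5616.22358709262,15
5620,5595.13695261579,15
5600,5578.34936490539,15
5580,5565.30536869269,15
5560,5554.80220772956,15
5540,5545.19779227044,15
5520,5534.69463130731,15
5500,5521.65063509461,15
5480,5504.86304738421,15
5460,5483.77641290738,15
5440,5458.57862063693,15
5420,5430.16841607689,15
5400,5400,15
5380,5369.8315839231,15
5360,5341.42137936307,15
5340,5316.22358709262,15
5320,5295.13695261579,15
5300,5278.34936490539,15
5280,5265.30536869269,15
5260,5254.80220772956,15
5240,5245.19779227044,15
5220,5234.69463130731,15
5200,5221.65063509461,15
5180,5204.86304738421,15
5160,5183.77641290738,15
5140,5158.57862063693,15
5120,5130.16841607689,15
5100,5100,15
5080,5069.8315839231,15
5060,5041.42137936307,15
5040,5016.22358709262,15
5020,4995.13695261579,15
5000,4978.34936490539,15
4980,4965.30536869269,15
4960,4954.80220772956,15
4940,4945.19779227044,15
4920,4934.69463130731,15
4900,4921.65063509461,15
4880,4904.86304738421,15
4860,4883.77641290738,15
4840,4858.57862063693,15
4820,4830.16841607689,15
4800,4800,15
4780,4769.8315839231,15
4760,4741.42137936307,15
4740,4716.22358709262,15
4720,4695.13695261579,15
4700,4678.34936490539,15
4680,4665.30536869269,15
4660,4654.80220772956,15
4640,4645.19779227044,15
4620,4634.69463130731,15
4600,4621.65063509461,15
4580,4604.86304738421,15
4560,4583.77641290738,15
4540,4558.57862063693,15
4520,4530.16841607689,15
4500,4500,15
4480,4469.8315839231,15
4460,4441.42137936307,15
4440,4416.22358709262,15
4420,4395.13695261579,15
4400,4378.34936490539,15
4380,4365.30536869269,15
4360,4354.80220772956,15
4340,4345.19779227044,15
4320,4334.69463130731,15
4300,4321.65063509461,15
4280,4304.86304738421,15
4260,4283.77641290738,15
4240,4258.57862063693,15
4220,4230.16841607689,15
4200,4200,15
4180,4169.8315839231,15
4160,4141.42137936307,15
4140,4116.22358709262,15
4120,4095.13695261579,15
4100,4078.34936490539,15
4080,4065.30536869269,15
4060,4054.80220772956,15
4040,4045.19779227044,15
4020,4034.69463130731,15
4000,4021.65063509461,15
3980,4004.86304738421,15
3960,3983.77641290738,15
3940,3958.57862063693,15
3920,3930.1684160769,15
3900,3900,15
3880,3869.8315839231,15
3860,3841.42137936307,15
3840,3816.22358709262,15
3820,3795.13695261579,15
3800,3778.34936490539,15
3780,3765.30536869269,15
3760,3754.80220772956,15
3740,3745.19779227044,15
3720,3734.69463130731,15
3700,3721.65063509461,15
3680,3704.86304738421,15
3660,3683.77641290738,15
3640,3658.57862063693,15
3620,3630.16841607689,15
3600,3600,15
3580,3569.8315839231,15
3560,3541.42137936307,15
3540,3516.22358709262,15
3520,3495.13695261579,15
3500,3478.34936490539,15
3480,3465.30536869269,15
3460,3454.80220772956,15
3440,3445.19779227044,15
3420,3434.69463130731,15
3400,3421.65063509461,15
3380,3404.86304738421,15
3360,3383.77641290738,15
3340,3358.57862063693,15
3320,3330.1684160769,15
3300,3300,15
3280,3269.8315839231,15
3260,3241.42137936307,15
3240,3216.22358709262,15
3220,3195.13695261579,15
3200,3178.34936490539,15
3180,3165.30536869269,15
3160,3154.80220772956,15
3140,3145.19779227044,15
3120,3134.69463130731,15
3100,3121.65063509461,15
3080,3104.86304738421,15
3060,3083.77641290738,15
3040,3058.57862063693,15
3020,3030.1684160769,15
3000,3000,15
2980,2969.8315839231,15
2960,2941.42137936307,15
2940,2916.22358709262,15
2920,2895.13695261579,15
2900,2878.34936490539,15
2880,2865.30536869269,15
2860,2854.80220772956,15
2840,2845.19779227044,15
2820,2834.69463130731,15
2800,2821.65063509461,15
2780,2804.86304738421,15
2760,2783.77641290738,15
2740,2758.57862063693,15
2720,2730.1684160769,15
2700,2700,15
2680,2669.8315839231,15
2660,2641.42137936307,15
2640,2616.22358709262,15
2620,2595.13695261579,15
2600,2578.34936490539,15
2580,2565.30536869269,15
2560,2554.80220772956,15
2540,2545.19779227044,15
2520,2534.69463130731,15
2500,2521.65063509461,15
2480,2504.86304738421,15
2460,2483.77641290738,15
2440,2458.57862063693,15
2420,2430.1684160769,15
2400,2400,15
2380,2369.8315839231,15
2360,2341.42137936307,15
2340,2316.22358709262,15
2320,2295.13695261579,15
2300,2278.34936490539,15
2280,2265.30536869269,15
2260,2254.80220772956,15
2240,2245.19779227044,15
2220,2234.69463130731,15
2200,2221.65063509461,15
2180,2204.86304738421,15
2160,2183.77641290738,15
2140,2158.57862063693,15
2120,2130.1684160769,15
2100,2100,15
2080,2069.8315839231,15
2060,2041.42137936307,15
2040,2016.22358709262,15
2020,1995.13695261579,15
2000,1978.34936490539,15
1980,1965.30536869269,15
1960,1954.80220772956,15
1940,1945.19779227044,15
1920,1934.69463130731,15
1900,1921.65063509461,15
1880,1904.86304738421,15
1860,1883.77641290738,15
1840,1858.57862063693,15
1820,1830.1684160769,15
1800,1800,15
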