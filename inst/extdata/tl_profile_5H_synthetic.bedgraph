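# synthetic stand-in turn-length profile for a 600 Mb chromosome
# emulating published barley 5H characteristics (turn lengths 20-38 Mb,
# longer turns in proximal regions); NOT measured data
5H_synthetic	0	5000000	20166667
5H_synthetic	5000000	10000000	20500000
5H_synthetic	10000000	15000000	20833333
5H_synthetic	15000000	20000000	21166667
5H_synthetic	20000000	25000000	21500000
5H_synthetic	25000000	30000000	21833333
5H_synthetic	30000000	35000000	22166667
5H_synthetic	35000000	40000000	22500000
5H_synthetic	40000000	45000000	22833333
5H_synthetic	45000000	50000000	23166667
5H_synthetic	50000000	55000000	23500000
5H_synthetic	55000000	60000000	23833333
5H_synthetic	60000000	65000000	24166667
5H_synthetic	65000000	70000000	24500000
5H_synthetic	70000000	75000000	24833333
5H_synthetic	75000000	80000000	25166667
5H_synthetic	80000000	85000000	25500000
5H_synthetic	85000000	90000000	25833333
5H_synthetic	90000000	95000000	26166667
5H_synthetic	95000000	100000000	26500000
5H_synthetic	100000000	105000000	26833333
5H_synthetic	105000000	110000000	27166667
5H_synthetic	110000000	115000000	27500000
5H_synthetic	115000000	120000000	27833333
5H_synthetic	120000000	125000000	28166667
5H_synthetic	125000000	130000000	28500000
5H_synthetic	130000000	135000000	28833333
5H_synthetic	135000000	140000000	29166667
5H_synthetic	140000000	145000000	29500000
5H_synthetic	145000000	150000000	29833333
5H_synthetic	150000000	155000000	30166667
5H_synthetic	155000000	160000000	30500000
5H_synthetic	160000000	165000000	30833333
5H_synthetic	165000000	170000000	31166667
5H_synthetic	170000000	175000000	31500000
5H_synthetic	175000000	180000000	31833333
5H_synthetic	180000000	185000000	32166667
5H_synthetic	185000000	190000000	32500000
5H_synthetic	190000000	195000000	32833333
5H_synthetic	195000000	200000000	33166667
5H_synthetic	200000000	205000000	33500000
5H_synthetic	205000000	210000000	33833333
5H_synthetic	210000000	215000000	34166667
5H_synthetic	215000000	220000000	34500000
5H_synthetic	220000000	225000000	34833333
5H_synthetic	225000000	230000000	35166667
5H_synthetic	230000000	235000000	35500000
5H_synthetic	235000000	240000000	35833333
5H_synthetic	240000000	245000000	36166667
5H_synthetic	245000000	250000000	36500000
5H_synthetic	250000000	255000000	36833333
5H_synthetic	255000000	260000000	37166667
5H_synthetic	260000000	265000000	37500000
5H_synthetic	265000000	270000000	37833333
5H_synthetic	270000000	275000000	37863636
5H_synthetic	275000000	280000000	37590909
5H_synthetic	280000000	285000000	37318182
5H_synthetic	285000000	290000000	37045455
5H_synthetic	290000000	295000000	36772727
5H_synthetic	295000000	300000000	36500000
5H_synthetic	300000000	305000000	36227273
5H_synthetic	305000000	310000000	35954545
5H_synthetic	310000000	315000000	35681818
5H_synthetic	315000000	320000000	35409091
5H_synthetic	320000000	325000000	35136364
5H_synthetic	325000000	330000000	34863636
5H_synthetic	330000000	335000000	34590909
5H_synthetic	335000000	340000000	34318182
5H_synthetic	340000000	345000000	34045455
5H_synthetic	345000000	350000000	33772727
5H_synthetic	350000000	355000000	33500000
5H_synthetic	355000000	360000000	33227273
5H_synthetic	360000000	365000000	32954545
5H_synthetic	365000000	370000000	32681818
5H_synthetic	370000000	375000000	32409091
5H_synthetic	375000000	380000000	32136364
5H_synthetic	380000000	385000000	31863636
5H_synthetic	385000000	390000000	31590909
5H_synthetic	390000000	395000000	31318182
5H_synthetic	395000000	400000000	31045455
5H_synthetic	400000000	405000000	30772727
5H_synthetic	405000000	410000000	30500000
5H_synthetic	410000000	415000000	30227273
5H_synthetic	415000000	420000000	29954545
5H_synthetic	420000000	425000000	29681818
5H_synthetic	425000000	430000000	29409091
5H_synthetic	430000000	435000000	29136364
5H_synthetic	435000000	440000000	28863636
5H_synthetic	440000000	445000000	28590909
5H_synthetic	445000000	450000000	28318182
5H_synthetic	450000000	455000000	28045455
5H_synthetic	455000000	460000000	27772727
5H_synthetic	460000000	465000000	27500000
5H_synthetic	465000000	470000000	27227273
5H_synthetic	470000000	475000000	26954545
5H_synthetic	475000000	480000000	26681818
5H_synthetic	480000000	485000000	26409091
5H_synthetic	485000000	490000000	26136364
5H_synthetic	490000000	495000000	25863636
5H_synthetic	495000000	500000000	25590909
5H_synthetic	500000000	505000000	25318182
5H_synthetic	505000000	510000000	25045455
5H_synthetic	510000000	515000000	24772727
5H_synthetic	515000000	520000000	24500000
5H_synthetic	520000000	525000000	24227273
5H_synthetic	525000000	530000000	23954545
5H_synthetic	530000000	535000000	23681818
5H_synthetic	535000000	540000000	23409091
5H_synthetic	540000000	545000000	23136364
5H_synthetic	545000000	550000000	22863636
5H_synthetic	550000000	555000000	22590909
5H_synthetic	555000000	560000000	22318182
5H_synthetic	560000000	565000000	22045455
5H_synthetic	565000000	570000000	21772727
5H_synthetic	570000000	575000000	21500000
5H_synthetic	575000000	580000000	21227273
5H_synthetic	580000000	585000000	20954545
5H_synthetic	585000000	590000000	20681818
5H_synthetic	590000000	595000000	20409091
5H_synthetic	595000000	600000000	20136364
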