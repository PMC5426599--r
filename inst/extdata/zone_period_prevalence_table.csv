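zone,cases,population
Ayrshire and Arran,81,373670
Dumfries and Galloway,10,151164
Forth Valley,14,275333
Grampian,2,62370
Greater Glasgow and Clyde,261,1102686
Highland,44,340903
Lanarkshire,90,666040
Orkney,0,21349
Tayside,2,142347
Western Isles,7,27684
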