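feature	detected	dm_pre_vs_in	dm_in_vs_post	dm_pre_vs_post
total	1320853	85726	92914	100421
cgi	628028	26422	28834	29862
cgi_shore	259488	20572	22559	25014
cgi_shelf	86548	7621	8489	9131
upstream	220380	7557	7797	8716
exon	290064	13384	14895	15729
intron	419870	31840	35490	38123
downstream	75956	5644	5912	6714
intergenic	314583	27301	28820	31139
qtl	57332	3930	4387	4691
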