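feature	detected	dm_pre_vs_in	dm_in_vs_post	dm_pre_vs_post
total	5884256	15940	14804	16893
cgi	1611528	2686	2456	2992
cgi_shore	1528834	4378	4102	4620
cgi_shelf	507135	1620	1518	1788
upstream	773667	1099	997	1281
exon	944488	1538	1387	1690
intron	2130322	6661	6251	7034
downstream	371205	1063	876	1102
intergenic	1664574	5579	5293	5786
qtl	251222	796	788	826
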