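rrp_id	length_bp	dataset	conf1	conf2	conf3	conf4
johSt_3550	825	illumina	346	15538	14865	966
johSt_12875	397	illumina	3293	27852	29759	556
johSt_14298	370	illumina	569	28789	26064	2606
johSt_20236	261	illumina	28545	829	717	30799
johSt_20316	171	illumina	731	24142	23248	255
johSt_3550	825	pacbio	60	579	736	93
johSt_12875	397	pacbio	12	882	994	6
johSt_14298	370	pacbio	5	958	890	4
johSt_20236	261	pacbio	943	8	5	872
johSt_20316	171	pacbio	0	585	545	0
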