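# Photosystem I cofactor annotations: chlorophyll chain, residue number,
# residue name and axial ligand for the special pair (P700), accessory
# (A_-1), primary acceptor (A_0) and connecting (A_C) chlorophylls of
# nine PS I structures.  axial_chain/axial_res/axial_aa give the residue
# coordinating the central Mg (PsaA -> chain A, PsaB -> chain B).
pdb_id	role	chain	res_seq	res_name	axial_chain	axial_res	axial_aa
1JB0	P700_A	A	1011	CLA	A	680	H
1JB0	P700_B	B	1021	CLA	B	660	H
1JB0	A_-1A	B	1012	CLA	B	591	N
1JB0	A_-1B	A	1022	CLA	A	604	N
1JB0	A_0A	A	1013	CLA	A	688	M
1JB0	A_0B	B	1023	CLA	B	668	M
1JB0	A_CA	A	1140	CLA	A	734	H
1JB0	A_CB	B	1239	CLA	B	718	H
5OY0	P700_A	A	1011	CLA	A	676	H
5OY0	P700_B	B	1021	CLA	B	651	H
5OY0	A_-1A	A	1012	CLA	B	582	N
5OY0	A_-1B	B	1022	CLA	A	600	N
5OY0	A_0A	A	1013	CLA	A	684	M
5OY0	A_0B	B	1023	CLA	B	659	M
5OY0	A_CA	A	1140	CLA	A	730	H
5OY0	A_CB	B	1239	CLA	B	709	H
6HQB	P700_A	A	1011	CLA	A	676	H
6HQB	P700_B	B	1021	CLA	B	651	H
6HQB	A_-1A	A	1012	CLA	B	582	N
6HQB	A_-1B	B	1022	CLA	A	600	N
6HQB	A_0A	A	1013	CLA	A	684	M
6HQB	A_0B	B	1023	CLA	B	659	M
6HQB	A_CA	A	1140	CLA	A	730	H
6HQB	A_CB	B	1239	CLA	B	709	H
6JO6	P700_A	A	801	CL0	A	676	H
6JO6	P700_B	B	802	CLA	B	655	H
6JO6	A_-1A	A	803	CLA	B	586	N
6JO6	A_-1B	A	854	CLA	A	601	N
6JO6	A_0A	A	802	CLA	A	684	M
6JO6	A_0B	B	803	CLA	B	663	M
6JO6	A_CA	A	842	CLA	A	730	H
6JO6	A_CB	B	840	CLA	B	713	H
6KMW	P700_A	A	801	CL0	A	689	H
6KMW	P700_B	B	803	CLA	B	662	H
6KMW	A_-1A	B	804	CLA	B	593	N
6KMW	A_-1B	B	801	CLA	A	613	N
6KMW	A_0A	B	802	CLA	A	697	M
6KMW	A_0B	B	805	CLA	B	670	M
6KMW	A_CA	A	841	CLA	A	743	H
6KMW	A_CB	B	841	CLA	B	720	H
6KMX	P700_A	A	801	CL0	A	709	H
6KMX	P700_B	B	801	CLA	B	664	H
6KMX	A_-1A	B	802	CLA	B	595	N
6KMX	A_-1B	A	802	CLA	A	633	N
6KMX	A_0A	A	803	CLA	A	717	M
6KMX	A_0B	B	803	CLA	B	672	M
6KMX	A_CA	A	843	CLA	A	763	H
6KMX	A_CB	B	840	CLA	B	721	H
6PNJ	P700_A	A	1011	CL0	A	713	H
6PNJ	P700_B	B	1021	CLA	B	661	H
6PNJ	A_-1A	A	1012	CLA	B	592	N
6PNJ	A_-1B	B	1022	CLA	A	637	N
6PNJ	A_0A	A	1013	CLA	A	721	M
6PNJ	A_0B	B	1023	CLA	B	669	M
6PNJ	A_CA	A	1140	CLA	A	767	H
6PNJ	A_CB	B	1239	CLA	B	718	H
7COY	P700_A	A	3101	G9R	A	678	H
7COY	P700_B	B	3003	CL7	B	657	H
7COY	A_-1A	B	3002	CL7	B	588	N
7COY	A_-1B	A	3103	CL7	A	602	N
7COY	A_0A	A	3102	PHO	A	686	M
7COY	A_0B	B	3004	PHO	B	665	L
7COY	A_CA	A	3143	CL7	A	732	H
7COY	A_CB	B	3026	CL7	B	715	H
5ZJI	P700_A	A	801	CL0	A	675	H
5ZJI	P700_B	B	802	CLA	B	654	H
5ZJI	A_-1A	A	803	CLA	B	585	N
5ZJI	A_-1B	A	854	CLA	A	599	N
5ZJI	A_0A	A	802	CLA	A	683	M
5ZJI	A_0B	B	803	CLA	B	662	M
5ZJI	A_CA	A	842	CLA	A	729	H
5ZJI	A_CB	B	840	CLA	B	712	H
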