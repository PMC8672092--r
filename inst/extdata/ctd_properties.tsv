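property	group1	group2	group3
hydrophobicity	R,K,E,D,Q,N	G,A,S,T,P,H,Y	C,L,V,I,M,F,W
vdw_volume	G,A,S,T,P,D,C	N,V,E,Q,I,L	M,H,K,F,R,Y,W
polarity	L,I,F,W,C,M,V,Y	P,A,T,G,S	H,Q,R,K,N,E,D
polarizability	G,A,S,D,T	C,P,N,V,E,Q,I,L	K,M,H,F,R,Y,W
charge	K,R	A,N,C,Q,G,H,I,L,M,F,P,S,T,W,Y,V	D,E
secondary_structure	E,A,L,M,Q,K,R,H	V,I,Y,C,W,F,T	G,N,P,S,D
solvent_accessibility	A,L,F,C,G,I,V,W	R,K,Q,E,N,D	M,S,P,T,H,Y
surface_tension	G,Q,D,N,A,H,R	K,T,S,E,C	I,L,M,F,P,W,Y,V
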