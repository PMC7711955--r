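variant,set,polyphen2,sift,mutation_taster,provean,ponp2,bs_printed
G3S,Nt,+++,+++,+++,+++,+++,3
G3D,Nt,+++,+++,+++,+++,++,2.8
L7P,Nt,+,+,+,+,+,1
L7R,Nt,+,+,+,+,+,1
V9I,Nt,+++,++,+,+++,++,2.2
T16M,Nt,+,+,+,+++,+,1.4
Y20N,Nt,++,+++,+,+++,++,2.2
A29T,Nt,+++,+++,+,+++,+++,2.6
P187S,P187,+++,+++,+++,+,++,2
P187E,P187,++,+,N.Det.,+,+,1.25
P187R,P187,+,+,+,+,+,1
P187L,P187,+,+,+,+,+,1
P187A,P187,++,+++,+,+,++,1.8
P187G,P187,++,+,N.Det.,+,+,1.25
P187T,P187,++,+++,+,+,+,1.6
K240Q,K240,+,+,+,+++,++,1.6
K240I,K240,+,+,+,+,++,1.2
K240E,K240,+,+,+,+++,++,1.6
K240T,K240,+,+,+,+++,++,1.6
K240H,K240,+,+,N.Det.,+++,++,1.75
K240A,K240,+,+,N.Det.,+++,++,1.75
K240G,K240,+,+,N.Det.,+,++,1.25
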