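variant,set,expression,thermal_stability,proteolysis,fad_binding,dic_binding,es_printed
G3S,Nt,+++,+++,+++,+++,+++,3
G3D,Nt,+++,+++,+++,+++,+++,3
L7P,Nt,+,,,,,1
L7R,Nt,+,,,,,1
V9I,Nt,+++,+++,+++,+++,+++,3
T16M,Nt,+++,++,++,+,+++,2.2
Y20N,Nt,+++,++,+++,++,+++,2.6
A29T,Nt,+++,+++,+++,++,+++,2.8
P187S,P187,+++,+,+,+,+,1.4
P187E,P187,+,,,,,1
P187R,P187,+,,,,,1
P187L,P187,+,,,,,1
P187A,P187,+++,++,+,++,++,2
P187G,P187,++,+,++,+++,++,2
P187T,P187,+++,++,+,++,+,1.8
K240Q,K240,+++,+++,++,++,++,2.4
K240I,K240,+++,+++,++,+++,+++,2.8
K240E,K240,+++,+++,+,++,++,2.2
K240T,K240,+++,+++,+++,++,+++,2.8
K240H,K240,+++,+++,++,++,+++,2.6
K240A,K240,+++,+++,+,+++,+++,2.6
K240G,K240,+++,+++,+,++,++,2.2
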