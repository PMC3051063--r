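parameter,value,fixed
a1,0.05,fixed
a2,20,fixed
a3,20,fixed
a4,20,fixed
a5,20,fixed
a6,0.9,free
a7,0.2,free
a8,0.9,free
a9,0.9,free
b1,1e-05,fixed
b2,1e-06,fixed
c1,2,fixed
c2,2,fixed
c3,0.02,fixed
c4,0.02,fixed
c5,0.9,free
c6,0.9,free
c7,0.01,fixed
c8,0.01,fixed
d1,6,fixed
d10,0.9,free
d2,0.1,fixed
d3,0.1,fixed
d4,0.1,fixed
d5,0.1,fixed
d6,2e-04,free
d7,0.066,free
d8,0.02,free
d9,0.9,free
e1,0.5,free
g3,0.9,free
g4,0.9,free
g5,0.001,free
g6,1e-05,free
g7,0.2,free
n1,0.2,free
n2,0.01,free
t1,0.409532956013168,free
t2,0.5,free
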