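// Compact (M,R) metabolism-replacement network, steady-state regime.
// Three enzymatic triples (binding / unbinding / catalysis) close the
// catalytic cycle f -> B -> p -> f; A is replenished by the environment.

k1 = 0.01;
k2 = 100;
k3 = 1;
l1 = 0.01;
l2 = 100;
l3 = 1;
m1 = 0.01;
m2 = 100;
m3 = 1;
d1 = 0;
d2 = 0.05;
d3 = 0.02426;

kineticLawOf r_k1 : k1 * A * f;
kineticLawOf r_k2 : k2 * fA;
kineticLawOf r_k3 : k3 * fA;
kineticLawOf r_l1 : l1 * B * p;
kineticLawOf r_l2 : l2 * pB;
kineticLawOf r_l3 : l3 * pB;
kineticLawOf r_m1 : m1 * f * B;
kineticLawOf r_m2 : m2 * Bf;
kineticLawOf r_m3 : m3 * Bf;
kineticLawOf r_d1 : d1 * B;
kineticLawOf r_d2 : d2 * f;
kineticLawOf r_d3 : d3 * p;

A = (r_k1, 1) <<;
B = (r_k3, 1) >> + (r_l1, 1) << + (r_l2, 1) >> + (r_m1, 1) << + (r_m2, 1) >> + (r_m3, 1) >> + (r_d1, 1) <<;
f = (r_k1, 1) << + (r_k2, 1) >> + (r_k3, 1) >> + (r_l3, 1) >> + (r_m1, 1) << + (r_m2, 1) >> + (r_d2, 1) <<;
p = (r_l1, 1) << + (r_l2, 1) >> + (r_l3, 1) >> + (r_m3, 1) >> + (r_d3, 1) <<;
fA = (r_k1, 1) >> + (r_k2, 1) << + (r_k3, 1) <<;
pB = (r_l1, 1) >> + (r_l2, 1) << + (r_l3, 1) <<;
Bf = (r_m1, 1) >> + (r_m2, 1) << + (r_m3, 1) <<;

constant A;

A[1000] <*> B[0] <*> f[1000] <*> p[0] <*> fA[0] <*> pB[0] <*> Bf[0]
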