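parameter,n_triples,n_quads
IVSd,584,547
LVIDd,579,550
LVIDs,572,537
LVPWd,579,547
LVEDV MOD biplane,583,534
LVESV MOD biplane,583,535
LVEF MOD biplane,583,531
LAESV MOD biplane,585,507
RA area A4C,497,480
RVIDd,412,372
LVSV MOD biplane,583,533
MV-Adur,371,326
MV-E,560,508
MV-A,494,433
DecT,501,446
e' lateral,547,458
e' septal,541,490
E/e' mean,511,388
a' lateral,492,408
a' septal,485,430
s' lateral,547,445
s' septal,549,459
TR Vmax,217,149
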