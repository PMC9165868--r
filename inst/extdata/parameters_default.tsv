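name	value	units	provenance	description
mu_mh_star	1e6	molec/(mL*s)	assumed	maximal HMGCR mRNA transcription rate
mu_mr_star	6e6	molec/(mL*s)	assumed	maximal LDLR mRNA transcription rate
mu_mp_star	1e6	molec/(mL*s)	table1	maximal PCSK9 mRNA transcription rate
delta_mh	4.48e-5	1/s	parent_model	HMGCR mRNA degradation rate
delta_mr	4.48e-5	1/s	parent_model	LDLR mRNA degradation rate
delta_mp	4.48e-5	1/s	table1	PCSK9 mRNA degradation rate
kappa_mh	8.21e16	molec/mL	parent_model	HMGCR gene-SREBP-2 binding affinity
kappa_mr	8.21e16	molec/mL	parent_model	LDLR gene-SREBP-2 binding affinity
kappa_mp	8.21e16	molec/mL	table1	PCSK9 gene-SREBP-2 binding affinity
s0	8.21e15	molec/mL	assumed	total SREBP-2 pool
kc	1e17	molec/mL	assumed	SREBP-2-cholesterol dissociation scale
xc	4	1	assumed	cholesterol molecules inactivating SREBP-2
xh	1	1	assumed	SREBP-2 binding sites on HMGCR gene
xr	1	1	assumed	SREBP-2 binding sites on LDLR gene
xp	1	1	table1	SREBP-2 binding sites on PCSK9 gene
mu_h	1e-1	1/s	assumed	HMGCR translation rate
mu_r	1e-1	1/s	assumed	LDLR translation rate
mu_p	1e-1	1/s	table1	PCSK9 translation rate
delta_h	1e-4	1/s	assumed	intracellular HMGCR degradation rate
delta_p	0	1/s	table1	intracellular PCSK9 degradation rate
delta_c	5e-5	1/s	assumed	intracellular cholesterol removal rate
gamma_r	1e-2	1/s	assumed	LDLR transport rate to the membrane
gamma_p	1e-2	1/s	table1	PCSK9 secretion rate to the extracellular space
gamma_l	1e-4	1/s	assumed	cholesterol extraction rate from internalised LDL
gamma_v	1e-4	1/s	assumed	cholesterol extraction rate from internalised VLDL
f	0.7	1	assumed	fraction of internalised receptors recycled
P	20	1	assumed	receptors per endocytic pit
beta_0	2.7e-3	1/s	assumed	internalisation rate of unbound pits
M_l	1	1	assumed	receptors covered per bound LDL
M_v	4	1	assumed	receptors covered per bound VLDL
M_p	1	1	table1	receptors covered per bound PCSK9
alpha_l	1e-16	mL/(molec*s)	assumed	LDL-LDLR binding rate
alpha_minus_l	1e-4	1/s	assumed	LDL-LDLR unbinding rate
alpha_v	5e-16	mL/(molec*s)	assumed	VLDL-LDLR binding rate
alpha_minus_v	1e-4	1/s	assumed	VLDL-LDLR unbinding rate
alpha_p	1e-17	mL/(molec*s)	table1	PCSK9-LDLR binding rate
alpha_minus_p	1e-4	1/s	table1	PCSK9-LDLR unbinding rate
beta_l	2.7e-3	1/s	parent_model	LDL internalisation rate
beta_v	2.7e-3	1/s	parent_model	VLDL internalisation rate
beta_p	2.7e-3	1/s	table1	PCSK9 internalisation rate
chi_v	1e-5	1/s	assumed	VLDL to LDL delipidation rate
omega_V	2.5e6	molec/(mL*s)	assumed	constant extracellular VLDL source
omega_P	0	molec/(mL*s)	assumed	baseline extracellular PCSK9 source
omega_A	0	molec/(mL*s)	assumed	baseline extracellular antibody source
omega_S	0	molec/(mL*s)	assumed	baseline extracellular statin source
R_l_chol	3000	1	assumed	cholesterol molecules per internalised LDL
R_v_chol	6000	1	assumed	cholesterol molecules per internalised VLDL
mu_c	1.4	1/s	assumed	HMGCR-driven cholesterol synthesis rate
eps_S	1e-14	mL/(molec*s)	table1	statin-HMGCR binding rate
eps_minus_S	1e-2	1/s	table1	statin-HMGCR unbinding rate
CL_S	1e-2	mL/s	table1	statin cell-uptake clearance
eps_p	1e-14	mL/(molec*s)	table1	antibody-PCSK9 binding rate
eps_minus_p	1e-3	1/s	table1	antibody-PCSK9 unbinding rate
W	500	1	assumed	extracellular to cellular volume ratio
J	1	1	assumed	nuclear compartment scaling constant
rf0	5e13	molec/mL	assumed	total surface receptor site capacity (also receptor scale)
sE0	1e12	molec/mL	assumed	statin reference scale
pE0_ref	1e12	molec/mL	assumed	PCSK9/antibody reference scale
tau	22321.428571428572	s	assumed	time scale (1/delta_mh)
m0	1e9	molec/mL	assumed	mRNA reference scale
c0	1e17	molec/mL	assumed	cholesterol reference scale (kc)
l0	1e11	molec/mL	assumed	LDL reference scale
v0	1e11	molec/mL	assumed	VLDL reference scale
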