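marker	display	modality	block	log_transform
amyloid_pet	Amyloid PET (Centiloid)	PET	core	FALSE
tau_pet	Tau PET (SUVR)	PET	core	FALSE
ab42_ab40_plasma	Abeta42/40 plasma	plasma	core	FALSE
ab42_ab40_csf	CSF Abeta42/40 (LUMIPULSE)	CSF	core	FALSE
ptau181_ab40_csf	CSF p-tau181/Abeta40 (LUMIPULSE)	CSF	core	FALSE
ttau_ab40_csf	CSF t-tau/Abeta40 (LUMIPULSE)	CSF	core	FALSE
pt111	CSF pT111/T111 occupancy	CSF	core	FALSE
pt153	CSF pT153/T153 occupancy	CSF	core	FALSE
pt175	CSF pT175/T175 occupancy	CSF	none	FALSE
pt181	CSF pT181/T181 occupancy	CSF	core	FALSE
ps199	CSF pS199/S199 occupancy	CSF	at8	FALSE
ps202	CSF pS202/S202 occupancy	CSF	at8	FALSE
pt205	CSF pT205/T205 occupancy	CSF	at8	FALSE
ps208	CSF pS208/S208 occupancy	CSF	core	FALSE
pt217	CSF pT217/T217 occupancy	CSF	core	FALSE
pt231	CSF pT231/T231 occupancy	CSF	core	FALSE
nfl_csf	CSF NfL	CSF	neurodegeneration	TRUE
nfl_plasma	Plasma NfL	plasma	neurodegeneration	TRUE
cortical_signature	MRI AD cortical signature (mm)	MRI	neurodegeneration	FALSE
ng_csf	CSF neurogranin	CSF	dysfunction	FALSE
snap25_csf	CSF SNAP-25	CSF	dysfunction	FALSE
vilip1_csf	CSF VILIP-1	CSF	dysfunction	FALSE
ykl40_csf	CSF YKL-40	CSF	dysfunction	FALSE
strem2_csf	CSF sTREM2	CSF	dysfunction	FALSE
cdr_sb	CDR Sum of Boxes	clinical	core	FALSE
mmse	MMSE	clinical	none	FALSE
prs	AD polygenic risk score	genetic	none	FALSE
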