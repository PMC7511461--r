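condition,icd10_prefix,weight
mi,I21,1
mi,I22,1
mi,I252,1
chf,I099,1
chf,I110,1
chf,I130,1
chf,I132,1
chf,I255,1
chf,I420,1
chf,I425,1
chf,I426,1
chf,I427,1
chf,I428,1
chf,I429,1
chf,I43,1
chf,I50,1
chf,P290,1
pvd,I70,1
pvd,I71,1
pvd,I731,1
pvd,I738,1
pvd,I739,1
pvd,I771,1
pvd,I790,1
pvd,I792,1
pvd,K551,1
pvd,K558,1
pvd,K559,1
pvd,Z958,1
pvd,Z959,1
cvd,G45,1
cvd,G46,1
cvd,H340,1
cvd,I60,1
cvd,I61,1
cvd,I62,1
cvd,I63,1
cvd,I64,1
cvd,I65,1
cvd,I66,1
cvd,I67,1
cvd,I68,1
cvd,I69,1
dementia,F00,1
dementia,F01,1
dementia,F02,1
dementia,F03,1
dementia,F051,1
dementia,G30,1
dementia,G311,1
copd,I278,1
copd,I279,1
copd,J40,1
copd,J41,1
copd,J42,1
copd,J43,1
copd,J44,1
copd,J45,1
copd,J46,1
copd,J47,1
copd,J60,1
copd,J61,1
copd,J62,1
copd,J63,1
copd,J64,1
copd,J65,1
copd,J66,1
copd,J67,1
copd,J684,1
copd,J701,1
copd,J703,1
rheumatic,M05,1
rheumatic,M06,1
rheumatic,M315,1
rheumatic,M32,1
rheumatic,M33,1
rheumatic,M34,1
rheumatic,M351,1
rheumatic,M353,1
rheumatic,M360,1
pud,K25,1
pud,K26,1
pud,K27,1
pud,K28,1
mild_liver,B18,1
mild_liver,K700,1
mild_liver,K701,1
mild_liver,K702,1
mild_liver,K703,1
mild_liver,K709,1
mild_liver,K713,1
mild_liver,K714,1
mild_liver,K715,1
mild_liver,K717,1
mild_liver,K73,1
mild_liver,K74,1
mild_liver,K760,1
mild_liver,K762,1
mild_liver,K763,1
mild_liver,K764,1
mild_liver,K768,1
mild_liver,K769,1
mild_liver,Z944,1
diabetes,E100,1
diabetes,E101,1
diabetes,E106,1
diabetes,E108,1
diabetes,E109,1
diabetes,E110,1
diabetes,E111,1
diabetes,E116,1
diabetes,E118,1
diabetes,E119,1
diabetes,E120,1
diabetes,E121,1
diabetes,E126,1
diabetes,E128,1
diabetes,E129,1
diabetes,E130,1
diabetes,E131,1
diabetes,E136,1
diabetes,E138,1
diabetes,E139,1
diabetes,E140,1
diabetes,E141,1
diabetes,E146,1
diabetes,E148,1
diabetes,E149,1
diabetes_complicated,E102,2
diabetes_complicated,E103,2
diabetes_complicated,E104,2
diabetes_complicated,E105,2
diabetes_complicated,E107,2
diabetes_complicated,E112,2
diabetes_complicated,E113,2
diabetes_complicated,E114,2
diabetes_complicated,E115,2
diabetes_complicated,E117,2
diabetes_complicated,E122,2
diabetes_complicated,E123,2
diabetes_complicated,E124,2
diabetes_complicated,E125,2
diabetes_complicated,E127,2
diabetes_complicated,E132,2
diabetes_complicated,E133,2
diabetes_complicated,E134,2
diabetes_complicated,E135,2
diabetes_complicated,E137,2
diabetes_complicated,E142,2
diabetes_complicated,E143,2
diabetes_complicated,E144,2
diabetes_complicated,E145,2
diabetes_complicated,E147,2
paralysis,G041,2
paralysis,G114,2
paralysis,G801,2
paralysis,G802,2
paralysis,G81,2
paralysis,G82,2
paralysis,G830,2
paralysis,G831,2
paralysis,G832,2
paralysis,G833,2
paralysis,G834,2
paralysis,G839,2
renal,I120,2
renal,I131,2
renal,N032,2
renal,N033,2
renal,N034,2
renal,N035,2
renal,N036,2
renal,N037,2
renal,N052,2
renal,N053,2
renal,N054,2
renal,N055,2
renal,N056,2
renal,N057,2
renal,N18,2
renal,N19,2
renal,N250,2
renal,Z490,2
renal,Z491,2
renal,Z492,2
renal,Z940,2
renal,Z992,2
cancer,C00,2
cancer,C01,2
cancer,C02,2
cancer,C03,2
cancer,C04,2
cancer,C05,2
cancer,C06,2
cancer,C07,2
cancer,C08,2
cancer,C09,2
cancer,C10,2
cancer,C11,2
cancer,C12,2
cancer,C13,2
cancer,C14,2
cancer,C15,2
cancer,C16,2
cancer,C17,2
cancer,C18,2
cancer,C19,2
cancer,C20,2
cancer,C21,2
cancer,C22,2
cancer,C23,2
cancer,C24,2
cancer,C25,2
cancer,C26,2
cancer,C30,2
cancer,C31,2
cancer,C32,2
cancer,C33,2
cancer,C34,2
cancer,C37,2
cancer,C38,2
cancer,C39,2
cancer,C40,2
cancer,C41,2
cancer,C43,2
cancer,C45,2
cancer,C46,2
cancer,C47,2
cancer,C48,2
cancer,C49,2
cancer,C50,2
cancer,C51,2
cancer,C52,2
cancer,C53,2
cancer,C54,2
cancer,C55,2
cancer,C56,2
cancer,C57,2
cancer,C58,2
cancer,C60,2
cancer,C61,2
cancer,C62,2
cancer,C63,2
cancer,C64,2
cancer,C65,2
cancer,C66,2
cancer,C67,2
cancer,C68,2
cancer,C69,2
cancer,C70,2
cancer,C71,2
cancer,C72,2
cancer,C73,2
cancer,C74,2
cancer,C75,2
cancer,C76,2
cancer,C81,2
cancer,C82,2
cancer,C83,2
cancer,C84,2
cancer,C85,2
cancer,C88,2
cancer,C90,2
cancer,C91,2
cancer,C92,2
cancer,C93,2
cancer,C94,2
cancer,C95,2
cancer,C96,2
cancer,C97,2
severe_liver,I850,3
severe_liver,I859,3
severe_liver,I864,3
severe_liver,I982,3
severe_liver,K704,3
severe_liver,K711,3
severe_liver,K721,3
severe_liver,K729,3
severe_liver,K765,3
severe_liver,K766,3
severe_liver,K767,3
metastatic,C77,6
metastatic,C78,6
metastatic,C79,6
metastatic,C80,6
hiv,B20,6
hiv,B21,6
hiv,B22,6
hiv,B24,6
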