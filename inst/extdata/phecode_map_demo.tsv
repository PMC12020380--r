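icd10	phecode	phenotype	category
E05.0	242.1	Graves' disease	endocrine/metabolic
E05.1	242.2	Toxic nodular goiter	endocrine/metabolic
E05.2	242.2	Toxic nodular goiter	endocrine/metabolic
E05	242	Thyrotoxicosis	endocrine/metabolic
E03	244	Hypothyroidism	endocrine/metabolic
E06	245	Thyroiditis	endocrine/metabolic
E04	246	Other thyroid disorders	endocrine/metabolic
E20	252.2	Hypoparathyroidism	endocrine/metabolic
E21.0	252.1	Hyperparathyroidism	endocrine/metabolic
E22	253.1	Pituitary hyperfunction	endocrine/metabolic
E10	250.1	Type 1 diabetes	endocrine/metabolic
E11	250.2	Type 2 diabetes	endocrine/metabolic
E86	276.5	Volume depletion	endocrine/metabolic
D50	280.1	Iron deficiency anemia	hematopoietic
A09	008	Intestinal infection	infectious diseases
A41	038	Septicemia	infectious diseases
F05	290.2	Delirium	mental disorders
F32	296.2	Depression	mental disorders
F41	300.1	Anxiety disorder	mental disorders
G30	290.1	Dementia	neurological
H02	374	Eyelid disorders	sense organs
H04	375	Lacrimal system disorders	sense organs
I10	401.1	Essential hypertension	circulatory system
I20	411.1	Angina pectoris	circulatory system
I21	411.2	Myocardial infarction	circulatory system
I25	411.4	Coronary atherosclerosis	circulatory system
I44	426.2	Cardiac conduction block	circulatory system
I48	427.21	Atrial fibrillation	circulatory system
I50	428.2	Heart failure	circulatory system
I63	433.21	Cerebral artery occlusion	circulatory system
I67	433.3	Cerebral ischemia	circulatory system
I95	458.9	Hypotension	circulatory system
J18	480.1	Pneumonia	respiratory
J44	496	Chronic airway obstruction	respiratory
K20	530.13	Esophagitis	digestive
K21	530.11	Gastroesophageal reflux disease	digestive
K52	558	Noninfectious gastroenteritis	digestive
K92	578	Gastrointestinal hemorrhage	digestive
M81	743.1	Osteoporosis	musculoskeletal
N04	580.2	Nephrotic syndrome	genitourinary
N17	585.1	Acute renal failure	genitourinary
N18	585.3	Chronic renal failure	genitourinary
N39.0	591	Urinary tract infection	genitourinary
C50	174.1	Breast cancer	neoplasms
C73	193	Thyroid cancer	neoplasms
D34	226	Benign thyroid tumor	neoplasms
O26	649	Pregnancy complication	pregnancy complications
Q21	747.1	Congenital heart anomaly	congenital anomalies
S72	800	Femur fracture	injuries & poisonings
T39	965	Analgesic poisoning	injuries & poisonings
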