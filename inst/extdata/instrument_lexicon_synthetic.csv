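instrument_id,canonical_name,acronyms,kind,condition_tag
eortc_qlq_c30,European Organisation for Research and Treatment of Cancer Quality of Life Questionnaire-Core 30,EORTC QLQ-C30;QLQ-C30,PROM,cancer
fact_g,Functional Assessment of Cancer Therapy - General,FACT-G,PROM,cancer
cancer_related_qol,Cancer-Related Quality of Life Scale,Cancer-Related QoL,PROM,cancer
hads,Hospital Anxiety and Depression Scale,HADS,PROM,mental health
c_vas,Cancer Visual Analogue Scale,C-VAS,PROM,cancer
nci_proq,National Cancer Institute Patient Questionnaire,NCI,PROM,cancer
eq_5d_5l,EuroQol 5-Dimension 5-Level,EQ-5D-5L,PROM,generic
eq_5d_3l,EuroQol 5-Dimension 3-Level,EQ-5D-3L,PROM,generic
pro_ctcae,Patient-Reported Outcomes version of the Common Terminology Criteria for Adverse Events,PRO-CTCAE,PROM,cancer
ipss,International Prostate Symptom Score,IPSS,PROM,prostate
sf36,Short Form 36 Health Survey,SF-36,PROM,generic
sf12,Short Form 12 Health Survey,SF-12,PROM,generic
eortc_qlq_lc13,EORTC Quality of Life Questionnaire Lung Cancer Module,EORTC QLQ-LC13;QLQ-LC13,PROM,lung
eortc_qlq_br23,EORTC Quality of Life Questionnaire Breast Cancer Module,EORTC QLQ-BR23;QLQ-BR23,PROM,breast
eortc_qlq_hn35,EORTC Quality of Life Questionnaire Head and Neck Module,EORTC QLQ-H&N35;QLQ-H&N35,PROM,head and neck
eortc_qlq_cr29,EORTC Quality of Life Questionnaire Colorectal Module,EORTC QLQ-CR29;QLQ-CR29,PROM,digestive
fact_b,Functional Assessment of Cancer Therapy - Breast,FACT-B,PROM,breast
fact_l,Functional Assessment of Cancer Therapy - Lung,FACT-L,PROM,lung
fact_p,Functional Assessment of Cancer Therapy - Prostate,FACT-P,PROM,prostate
facit_f,Functional Assessment of Chronic Illness Therapy - Fatigue,FACIT-F,PROM,fatigue
fss,Fatigue Severity Scale,FSS,PROM,fatigue
bfi,Brief Fatigue Inventory,BFI,PROM,fatigue
bpi,Brief Pain Inventory,BPI,PROM,pain
mdasi,MD Anderson Symptom Inventory,MDASI,PROM,cancer
esas,Edmonton Symptom Assessment System,ESAS,PROM,palliative
phq9,Patient Health Questionnaire-9,PHQ-9,PROM,mental health
gad7,Generalized Anxiety Disorder 7-item scale,GAD-7,PROM,mental health
psqi,Pittsburgh Sleep Quality Index,PSQI,PROM,sleep
stai,State-Trait Anxiety Inventory,STAI,PROM,mental health
cesd,Center for Epidemiologic Studies Depression Scale,CES-D,PROM,mental health
mfi20,Multidimensional Fatigue Inventory,MFI-20,PROM,fatigue
epic,Expanded Prostate Cancer Index Composite,EPIC,PROM,prostate
promis_gh,PROMIS Global Health,PROMIS-GH,PROM,generic
whoqol_bref,World Health Organization Quality of Life Brief Version,WHOQOL-BREF,PROM,generic
qlq_stO22,EORTC Quality of Life Questionnaire Gastric Module,EORTC QLQ-STO22;QLQ-STO22,PROM,digestive
moriskey_mmas8,Morisky Medication Adherence Scale,MMAS-8,PROM,adherence
psq18,Patient Satisfaction Questionnaire Short Form,PSQ-18,PREM,care experience
cahps,Consumer Assessment of Healthcare Providers and Systems,CAHPS,PREM,care experience
ppe15,Picker Patient Experience Questionnaire,PPE-15,PREM,care experience
fft,National Health Service Friends and Family Test,FFT,PREM,care experience
kidney_prem,Kidney Patient Reported Experience Measure,Kidney PREM,PREM,renal
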