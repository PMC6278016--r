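# Disorder terms (Problem part of the Patient element).
diabetes
hypertension
cancer
breast cancer
lung cancer
prostate cancer
colorectal cancer
ovarian cancer
leukemia
lymphoma
melanoma
stroke
myocardial infarction
heart failure
angina
arrhythmia
atrial fibrillation
asthma
copd
bronchitis
pneumonia
influenza
tuberculosis
sepsis
hepatitis
cirrhosis
pancreatitis
appendicitis
arthritis
osteoarthritis
rheumatoid arthritis
osteoporosis
fracture
fractures
spasticity
multiple sclerosis
epilepsy
seizures
migraine
headache
dementia
alzheimer disease
parkinson disease
depression
anxiety
schizophrenia
bipolar disorder
insomnia
obesity
anemia
glaucoma
cataract
psoriasis
eczema
dermatitis
ulcer
ulcers
low back pain
back pain
chronic pain
neuropathy
nephropathy
renal failure
kidney disease
hypothyroidism
hyperthyroidism
hypercholesterolemia
spinal cord injury
brain injury
trauma
infection
infections
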