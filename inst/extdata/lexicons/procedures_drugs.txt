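# Procedure, device and drug terms (Intervention element).
surgery
surgical resection
chemotherapy
radiotherapy
radiation therapy
immunotherapy
physiotherapy
psychotherapy
acupuncture
massage
exercise training
rehabilitation
counseling
screening
vaccination
vaccine
transplantation
dialysis
laparoscopy
endoscopy
colonoscopy
biopsy
angioplasty
stent
stenting
bypass
catheter
catheterization
defibrillator
pacemaker
ventilation
intubation
anesthesia
analgesia
injection
infusion
supplementation
placebo
aspirin
ibuprofen
paracetamol
acetaminophen
morphine
codeine
ketamine
propofol
lidocaine
metformin
insulin
glipizide
statin
atorvastatin
simvastatin
warfarin
heparin
clopidogrel
lisinopril
enalapril
amlodipine
atenolol
metoprolol
furosemide
omeprazole
prednisone
dexamethasone
methotrexate
cisplatin
doxorubicin
tamoxifen
trastuzumab
fluoxetine
sertraline
risperidone
olanzapine
gabapentin
tizanidine
baclofen
antibiotics
penicillin
amoxicillin
azithromycin
vertebroplasty
kyphoplasty
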