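# Demographic / Patient-element cues: age, race, gender and group words.
patient
patients
men
women
man
woman
male
males
female
females
adult
adults
child
children
infant
infants
neonates
newborns
toddlers
adolescent
adolescents
teenagers
elderly
seniors
boys
girls
age
aged
ages
gender
sex
race
ethnicity
caucasian
hispanic
asian
african
american
veterans
residents
smokers
nonsmokers
pregnant
postmenopausal
premenopausal
volunteers
participants
subjects
individuals
persons
people
cohort
inpatients
outpatients
survivors
adults aged
years old
middle-aged
young adults
older adults
nursing home residents
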