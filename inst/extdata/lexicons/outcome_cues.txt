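# Outcome cue words. This list is the package's own construction: the
# composition of the outcome keyword list used with the original feature
# set was never published.
mortality
survival
improvement
improved
improving
reduction
reduced
decrease
decreased
increase
increased
outcome
outcomes
efficacy
effectiveness
response
responders
remission
relapse
recurrence
adverse events
adverse effects
side effects
complications
toxicity
tolerability
safety
quality of life
pain relief
relief
symptom relief
score
scores
rate
rates
ratio
risk
risks
hazard ratio
odds ratio
relative risk
confidence interval
significant
significantly
nonsignificant
benefit
benefits
harm
recovery
readmission
hospitalization
discharge
duration of stay
progression
progression-free
event-free
cure
failure rate
success rate
improvement rate
mean difference
follow-up
endpoint
endpoints
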