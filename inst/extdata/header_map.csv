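variant,common
OBJECTIVE,OBJECTIVE
OBJECTIVES,OBJECTIVE
AIM,OBJECTIVE
AIMS,OBJECTIVE
AIM OF THE STUDY,OBJECTIVE
BACKGROUND AND OBJECTIVES,OBJECTIVE
BACKGROUND AND OBJECTIVE,OBJECTIVE
BACKGROUND AND AIMS,OBJECTIVE
CONTEXT,OBJECTIVE
PURPOSE,OBJECTIVE
GOAL,OBJECTIVE
GOALS,OBJECTIVE
INTRODUCTION,OBJECTIVE
RATIONALE,OBJECTIVE
STUDY OBJECTIVE,OBJECTIVE
METHOD,METHOD
METHODS,METHOD
DESIGN,METHOD
DESIGN AND METHODS,METHOD
STUDY DESIGN,METHOD
STUDY DESIGN AND METHODS,METHOD
METHODS AND MATERIALS,METHOD
MATERIALS AND METHODS,METHOD
PATIENT(S),METHOD
PATIENT,METHOD
PATIENTS,METHOD
PATIENTS AND METHODS,METHOD
PARTICIPANTS,METHOD
SUBJECTS,METHOD
POPULATION,METHOD
INTERVENTION,METHOD
INTERVENTIONS,METHOD
INTERVENTION(S),METHOD
SETTING,METHOD
SETTING AND PARTICIPANTS,METHOD
PROCEDURE,METHOD
PROCEDURES,METHOD
MEASUREMENTS,METHOD
RESULTS,RESULTS
RESULT,RESULTS
FINDINGS,RESULTS
MAIN RESULTS,RESULTS
MAIN FINDINGS,RESULTS
OUTCOME MEASURES,RESULTS
OUTCOME MEASURE(S),RESULTS
MAIN OUTCOME MEASURES,RESULTS
MAIN OUTCOME MEASURE(S),RESULTS
OUTCOMES,RESULTS
OBSERVATIONS,RESULTS
CONCLUSION,CONCLUSION
CONCLUSIONS,CONCLUSION
CONCLUSION(S),CONCLUSION
DISCUSSION,CONCLUSION
IMPLICATIONS,CONCLUSION
SUMMARY,CONCLUSION
INTERPRETATION,CONCLUSION
COMMENT,CONCLUSION
RELEVANCE,CONCLUSION
CLINICAL RELEVANCE,CONCLUSION
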