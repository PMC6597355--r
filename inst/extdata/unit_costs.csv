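category,setting,unit,cost_gbp,index_trauma
outpatient,hospital,attendance,135,FALSE
emergency_dept,hospital,attendance,124,TRUE
ambulance,hospital,callout,236,TRUE
gp_surgery,community,visit,45,FALSE
gp_home_visit,community,visit,78,FALSE
district_nurse,community,visit,39,FALSE
counsellor,community,session,43,FALSE
educational_psychologist,community,session,90,FALSE
social_services,community,contact,25,FALSE
medications,community,prescription,10,FALSE
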