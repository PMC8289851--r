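"column","type","role","units","description"
"prior_uterine_incision_or_cesarean","boolean","assessment","","Prior cesarean birth or other uterine incision"
"known_bleeding_disorder","boolean","assessment","","Known bleeding disorder (treated as coagulopathy)"
"multiple_gestation","boolean","assessment","","Non-singleton pregnancy"
"labor_induction","boolean","assessment","","Induction of labor"
"large_uterine_fibroids","boolean","assessment","","Large uterine fibroids"
"chorioamnionitis","boolean","assessment","","Chorioamnionitis"
"fetal_demise","boolean","assessment","","Fetal demise"
"family_history_pph_first_degree","boolean","assessment","","First-degree relative with postpartum hemorrhage"
"polyhydramnios","boolean","assessment","","Polyhydramnios"
"active_bleeding_more_than_show","boolean","assessment","","Active bleeding greater than bloody show"
"suspected_accreta_or_percreta","boolean","assessment","","Suspected placenta accreta or percreta"
"placenta_previa_or_low_lying","boolean","assessment","","Placenta previa or low-lying placenta"
"known_coagulopathy","boolean","assessment","","Known coagulopathy"
"prior_vaginal_births","count","assessment","","Number of previous vaginal births"
"prior_pph_count","count","assessment","","Number of previous postpartum hemorrhages"
"bmi","numeric","assessment","kg/m2","Body mass index at delivery (empty if unknown)"
"estimated_fetal_weight","numeric","assessment","kg","Estimated fetal weight (empty if unknown)"
"hematocrit","numeric","assessment","%","Hematocrit (empty if unknown)"
"platelets","numeric","assessment","per uL","Platelet count (empty if unknown)"
"ebl_ml","numeric","outcome","mL","Estimated blood loss, gravimetric (empty if unknown)"
"prbc_units","count","outcome","units","Packed red blood cell units transfused"
"icu_admission","boolean","outcome","","Admitted to an intensive care unit"
"hysterectomy","boolean","outcome","","Peripartum hysterectomy"
"dilation_and_curettage","boolean","outcome","","Dilation and curettage"
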