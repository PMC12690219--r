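"field","provenance","note"
"discount_rate","paper_main_text",""
"wtp","paper_main_text",""
"wtp_secondary","paper_main_text",""
"start_age","paper_main_text",""
"max_age","synthetic_stand_in",""
"ai_years","paper_main_text",""
"cancer_transition_fits","synthetic_stand_in",""
"fracture_rate_curves","synthetic_stand_in",""
"fracture_rate_scale","synthetic_stand_in",""
"gradient_rr_per_sd","synthetic_stand_in",""
"rr_subsequent_fracture","synthetic_stand_in",""
"p_bedridden_after_hip","synthetic_stand_in",""
"hip_fracture_mortality_hr","synthetic_stand_in",""
"background_mortality","synthetic_stand_in",""
"bmd_baseline","synthetic_stand_in",""
"bmd_loss_on_ai","synthetic_stand_in",""
"bmd_loss_natural","synthetic_stand_in",""
"zscore_reference","synthetic_stand_in",""
"young_adult_age","synthetic_stand_in",""
"treatment_rr","synthetic_stand_in",""
"treatment_duration","paper_main_text","5 y alendronate/denosumab, 3 y zoledronate: printed constants"
"residual_duration","synthetic_stand_in",""
"adherence","paper_main_text","base value is a stand-in; the 72%/54% scenario values are printed constants"
"risk_modifiers","synthetic_stand_in",""
"utilities","synthetic_stand_in",""
"costs","synthetic_stand_in",""
"psa","synthetic_stand_in",""
"meta","paper_main_text",""
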