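"section","code","group","domain","values","consumers"
"item","adl_hygiene","adl","adl","0|1|2|3|4|5|6|8","adl_hierarchy;institutional_risk"
"item","adl_toilet_use","adl","adl","0|1|2|3|4|5|6|8","adl_hierarchy"
"item","adl_locomotion","adl","adl","0|1|2|3|4|5|6|8","adl_hierarchy"
"item","adl_eating","adl","adl","0|1|2|3|4|5|6|8","adl_hierarchy;cps"
"item","comatose","cognition","binary","0|1","cps"
"item","short_term_memory_problem","cognition","binary","0|1","cps;geriatric_screener"
"item","decision_making","cognition","scale3","0|1|2|3","cps;geriatric_screener"
"item","making_self_understood","cognition","scale3","0|1|2|3","cps"
"item","verbally_abusive","behavior","binary","0|1","behavior_disturbance"
"item","physically_abusive","behavior","binary","0|1","behavior_disturbance"
"item","socially_inappropriate","behavior","binary","0|1","behavior_disturbance"
"item","resists_care","behavior","binary","0|1","behavior_disturbance"
"item","decision_making_decline","clinical","binary","0|1","tree"
"item","medication_management_problem","clinical","binary","0|1","tree;geriatric_screener"
"item","pressure_ulcer","clinical","binary","0|1","tree"
"item","fall_recent","clinical","binary","0|1","tree"
"item","meal_preparation_problem","clinical","binary","0|1","tree;geriatric_screener;institutional_risk"
"item","swallowing_difficulty","clinical","binary","0|1","tree"
"item","prior_nursing_home","risk","binary","0|1","institutional_risk"
"item","goes_out","risk","binary","0|1","institutional_risk"
"item","bladder_incontinence","risk","binary","0|1","institutional_risk"
"item","dx_dementia","risk","binary","0|1","institutional_risk"
"item","dx_alzheimers","risk","binary","0|1","institutional_risk"
"item","dx_multiple_sclerosis","risk","binary","0|1","institutional_risk"
"item","dx_head_trauma","risk","binary","0|1","institutional_risk"
"item","bathing_problem","risk","binary","0|1","institutional_risk"
"item","delirium_easily_distracted","risk","binary","0|1","institutional_risk"
"item","delirium_disorganized_speech","risk","binary","0|1","institutional_risk"
"item","delirium_mental_function_varies","risk","binary","0|1","institutional_risk"
"item","delirium_acute_change","risk","binary","0|1","institutional_risk"
"item","shopping_problem","risk","binary","0|1","institutional_risk"
"episode","patient_id","episode","string","",""
"episode","sex","episode","enum","woman|man",""
"episode","age_group","episode","enum","75_79|80_84|85_89|90_plus",""
"episode","lived_alone","episode","binary","",""
"episode","prior_hosp_90d","episode","binary","",""
"episode","reason","episode","enum","new_problem|exacerbation|both",""
"episode","dxgrp_neoplasms","episode","binary","",""
"episode","dxgrp_mental_behavioral","episode","binary","",""
"episode","dxgrp_respiratory","episode","binary","",""
"episode","discharge_outcome","episode","enum","home|institution|dead|other",""
"episode","one_year_outcome","episode","enum","home|institution|dead|other",""
"episode","days_to_event","episode","integer","",""
"episode","event_died","episode","binary","",""
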