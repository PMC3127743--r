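# Reference encoding of the acute-care priority-level decision tree.
#
# The tree is data, not code: rules are evaluated in order,
# first-match-wins, against the classifier vector of one assessment
# (fields: adl, cps, behavior, decision_decline, medication_problem,
# pressure_ulcer, fall, meal_prep_problem, swallowing_difficulty,
# inst_risk_count, inst_risk_active, screener). Conditions are restricted
# expressions over those fields using comparison operators and & | ! ().
# Any vector matching no rule receives default_level. Every threshold here
# can be revised without code changes; outputs carry the version string
# below for provenance.
version: maple-ac-reference-1.0
default_level: low
rules:
  - name: very_high_severe_with_institutional_risk
    level: very_high
    condition: inst_risk_active & (adl >= 4 | cps >= 4 | behavior)
  - name: high_core_impairment_or_risk
    level: high
    condition: adl >= 3 | cps >= 3 | behavior | pressure_ulcer | inst_risk_active
  - name: moderate_clinical_findings
    level: moderate
    condition: fall | swallowing_difficulty | medication_problem | decision_decline | adl >= 1 | cps >= 1
  - name: mild_screener_findings
    level: mild
    condition: screener >= 1 | meal_prep_problem
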