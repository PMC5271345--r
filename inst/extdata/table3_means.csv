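item,category,meld,meso,ukeld,imeld,refit_meld,refit_meld_na,up_meld,meld_na,peld
inception_cohort_established,internal_validity,0.67,1,1,1,1,1,1,1,1
inception_cohort_followed_up,internal_validity,1,1,1,1,0.67,0.67,1,1,1
baseline_data_collected_prospectively,internal_validity,1,0.33,0.67,0.33,0.67,0.67,0.67,0.67,0.67
candidate_prognostic_factors_clearly_defined,internal_validity,0.67,0.67,0.67,0.67,0.67,0.67,0.67,0.67,1
multi_centre_population,external_validity,2,0,2,2,2,2,2,2,2
adequate_description,external_validity,1.34,0.67,2,1.34,1.34,1.34,1.34,1.34,1.34
continuous_variables,statistical_validity,0.67,0.67,0.67,0.67,1,1,0.67,0.67,1
sample_size_adequate,statistical_validity,1,0.67,1,0.67,1,1,1,1,1
collinearity_assessed,statistical_validity,0,0,0.33,0,0.33,0.33,0.33,0,0
missing_values,statistical_validity,0.33,0,0,0,0,0,0,0,0.67
assumptions_of_final_model_tested,evaluation_of_model,0.67,1,1,1,1,1,1,0.67,0.67
sensitivity_to_influential_observations,evaluation_of_model,0.67,1,0.33,1,0,0,0.33,0.33,1
model_validated_internal,evaluation_of_model,0.33,1,0.33,1,0,0,0.33,0.33,1
model_validated_external,evaluation_of_model,0.33,0.33,1,0.67,1,1,1,1,0.67
factors_available_in_clinical_practice,practicality,1,1,1,1,1,1,1,1,1
final_model_described_sufficiently,practicality,1,1,1,0.67,1,1,1,1,0.67
precision_of_predictions,practicality,0.67,1,1,1,1,1,0.67,0.67,0.67
wide_generalisability,practicality,1,0.67,1,1,1,1,1,1,0.67
printed_total,,14.32,11,16,14.02,15.01,15.01,15.01,14.35,15.36
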