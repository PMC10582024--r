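quantity,numerator,denominator
biologic_reports_of_all_reports,62883,21161249
case_reports_of_biologic_reports,1964,62883
serious_reports_of_biologic_reports,22995,62883
serious_reports_of_case_reports,1889,1964
omalizumab_anaphylactic_reaction_of_drug_total,1437,32457
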