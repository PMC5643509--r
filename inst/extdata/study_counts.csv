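quantity,value
total_monitored_nests,398
uniparental_cases,70
uniparental_nests,68
female_cases,14
known_outcome_nests,55
hatched_nests,15
depredated_nests,4
deserted_nests,36
cases_with_known_start,69
cases_start_after_period,7
cases_natural,54
cases_post_capture,13
cases_removal,3
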