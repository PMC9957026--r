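stage_name,count_in,count_out
automated_eligibility_screen,141762,1684
manual_confirmation_and_invitation,1684,902
eligible_survey_responses,902,146
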