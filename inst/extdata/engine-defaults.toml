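initial_delay_s = 90
delay_step_s = 10
training_increment_s = 10
response_timeout_s = 60
feedback_duration_s = 5
assessment_max_questions = 10
assessment_max_time_s = 1800
training_max_questions = 10
min_delay_s = 10
show_feedback_in_assessment = false
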