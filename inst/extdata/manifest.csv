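file,md5
table1_56q_screening.csv,9fa1561b546eb534af7c47d0c3692444
table2_pre_questions.csv,e1fa4f09cf75da21754518dbb49e00cf
table3_pre_validation.csv,526aa9efdd5e6585224deb6bc767618a
pre_question_set.json,d20ca3011a4245799d7012586531dac5
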