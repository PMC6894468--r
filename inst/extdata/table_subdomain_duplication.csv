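# Duplication of engagement among six Exercise and Sport sub-domains,
# re-keyed from the published summary table; base is the 1261 Exercise and
# Sport engagers of a 2307-adult time-use recall study. The Average and
# Expected footer rows are the published (rounded) values.
activity,prevalence,Gym,Non-Team Sports,Team Sports,Active Play,Games,Dance
Gym,60,,34,19,6,4,5
Non-Team Sports,41,49,,23,7,5,6
Team Sports,14,46,38,,5,8,3
Active Play,10,38,28,13,,6,5
Games,7,32,30,27,8,,4
Dance,7,43,36,12,7,5,
Average,,42,33,19,7,5,5
Expected,,48,32,11,8,6,6
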