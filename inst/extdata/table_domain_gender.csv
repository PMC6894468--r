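# Gender composition of everyday-domain engagers (percent of each
# activity's engagers who are male/female) with published deviations from
# the cross-activity average, re-keyed from a 2307-adult time-use study.
# Population split: 44% male, 56% female.
activity,n,male,female,dev_male,dev_female
Sleep,2307,44,56,0,0
Self-care,2306,44,56,0,0
Social,2167,43,57,-1,1
Passive Transport,2154,44,56,0,0
Screen Time,2125,44,56,0,0
Chores,2107,42,58,-2,2
Work and Study,2026,44,56,0,0
Quiet Time,2011,43,57,-1,1
Active Transport,1984,43,57,-1,1
Exercise and Sport,1261,48,52,4,-4
Cultural,313,40,60,-4,4
Average,,44,56,,
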