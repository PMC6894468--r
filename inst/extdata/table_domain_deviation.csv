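# Deviations (observed duplication minus column-average duplication, in
# percentage points) among 11 everyday activity domains, re-keyed from the
# published deviation table of a time-use recall study of 2307 adults.
# The authors computed on unrounded data, so a few cells differ by 1 pp
# from what the rounded duplication table reproduces.
activity,prevalence,Sleep,Self-care,Social,Passive Transport,Screen Time,Chores,Work and Study,Quiet Time,Active Transport,Exercise and Sport,Cultural
Sleep,100,,0,-1,-1,0,-1,-1,-2,-1,-1,0
Self-care,100,0,,-1,-1,0,-1,-1,-2,-1,-1,0
Social,94,0,0,,1,0,0,0,0,0,-1,0
Passive Transport,93,0,0,0,,0,0,0,-1,0,0,0
Screen Time,92,0,0,-1,0,,0,-1,-1,-1,-1,-1
Chores,91,0,0,0,0,1,,-1,0,0,-2,0
Work and Study,88,0,0,0,0,0,0,,0,0,2,0
Quiet Time,87,0,0,0,0,1,1,1,,1,0,1
Active Transport,86,0,0,1,1,1,0,1,1,,1,0
Exercise and Sport,55,0,0,0,1,0,-2,4,0,1,,1
Cultural,14,0,0,2,0,-3,2,0,5,1,3,
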