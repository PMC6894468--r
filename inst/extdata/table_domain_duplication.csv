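# Duplication of engagement among 11 everyday activity domains, re-keyed
# from the published summary table of a time-use recall study of 2307
# Australian and New Zealand adults. Cell [A,B] = % of A's engagers who
# also engaged in B over the recall window; diagonal blank. The Average
# and Expected footer rows are the published (rounded) values.
activity,prevalence,Sleep,Self-care,Social,Passive Transport,Screen Time,Chores,Work and Study,Quiet Time,Active Transport,Exercise and Sport,Cultural
Sleep,100,,100,94,93,92,91,88,87,86,55,14
Self-care,100,100,,94,93,92,91,88,87,86,55,14
Social,94,100,100,,95,92,92,89,89,88,55,14
Passive Transport,93,100,100,95,,93,92,89,88,87,55,14
Screen Time,92,100,100,94,94,,92,88,88,87,55,13
Chores,91,100,100,95,94,93,,88,89,87,54,14
Work and Study,88,100,100,95,95,92,92,,89,88,58,14
Quiet Time,87,100,100,95,94,93,93,90,,89,55,15
Active Transport,86,100,100,96,95,93,92,90,90,,56,14
Exercise and Sport,55,100,100,95,95,93,90,93,89,89,,15
Cultural,14,100,100,97,94,89,94,89,94,89,58,
Average,,100,100,95,94,92,92,89,89,87,56,14
Expected,,100,100,95,94,93,92,89,88,87,55,14
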