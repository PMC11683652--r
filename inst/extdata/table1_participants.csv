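user,age_when_posting,age_at_stroke,time_since_stroke,sex,identity,times_metaphor_used,total_posts,superuser
A,54,46,8,F,survivor,51,4932,yes
B,67,55,12,M,survivor,2,542,yes
C,67,67,0,F,survivor,1,178,yes
D,55,55,0,M,survivor,1,19,no
E,59,49,10,F,caregiver,1,2,no
F,42,40,2,F,survivor,3,291,yes
G,50,47,3,M,survivor,1,58,no
H,1,1,0,F,caregiver,1,27,no
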