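group,type,n,arrhythmia_count,deceleration_count,complex_count
CARDIAC,Flat,41,13,3,0
CARDIAC,Hack,42,21,9,0
CARDIAC,Trot,7,1,1,0
CARDIAC,Jumping,29,14,4,1
CARDIAC,XC_School,7,5,4,0
CARDIAC,Gallop,60,43,13,4
CARDIAC,Competition,16,12,2,0
NON_CARDIAC,Flat,168,16,2,0
NON_CARDIAC,Hack,35,6,1,0
NON_CARDIAC,Trot,29,5,2,0
NON_CARDIAC,Jumping,74,21,9,0
NON_CARDIAC,XC_School,29,6,2,0
NON_CARDIAC,Gallop,191,81,31,8
NON_CARDIAC,Competition,9,6,3,0
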