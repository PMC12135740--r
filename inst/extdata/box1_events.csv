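workout_id,group,type,kind,run_length,phase,morphology
B01,CARDIAC,Gallop,triplet,3,exercise,narrow
B01,CARDIAC,Gallop,run,6,exercise,narrow
B02,CARDIAC,Gallop,triplet,3,exercise,narrow
B03,CARDIAC,Gallop,triplet,3,exercise,narrow
B04,CARDIAC,Gallop,triplet,3,exercise,narrow
B05,CARDIAC,Jumping,triplet,3,exercise,narrow
B06,NON_CARDIAC,Gallop,triplet,3,exercise,narrow
B06,NON_CARDIAC,Gallop,triplet,3,exercise,narrow
B07,NON_CARDIAC,Gallop,triplet,3,exercise,narrow
B08,NON_CARDIAC,Gallop,triplet,3,exercise,narrow
B09,NON_CARDIAC,Gallop,triplet,3,deceleration,narrow
B10,NON_CARDIAC,Gallop,triplet,3,deceleration,narrow
B11,NON_CARDIAC,Gallop,triplet,3,deceleration,wide
B12,NON_CARDIAC,Gallop,paf,40,exercise,narrow
B13,NON_CARDIAC,Gallop,paf,40,exercise,narrow
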