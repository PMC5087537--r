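scheme,classifier,jump,left,right,forward,backward
kfold,jump,27,8,7,9,12
kfold,left,4,18,5,7,3
kfold,right,13,15,16,16,18
kfold,forward,6,5,4,17,5
kfold,backward,7,6,5,2,17
holdout,jump,7,1,4,2,1
holdout,left,3,5,2,1,4
holdout,right,2,5,8,4,2
holdout,forward,1,3,2,4,1
holdout,backward,2,1,0,1,2
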