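backend,motion,tp,pos_total,fp,neg_total
decision_tree,jump,813,895,75,2880
decision_tree,left,914,954,36,2821
decision_tree,right,806,901,84,2874
decision_tree,forward,470,510,47,3265
decision_tree,backward,445,515,60,3260
knn,jump,870,895,38,2880
knn,left,939,954,34,2821
knn,right,881,901,77,2874
knn,forward,498,510,39,3265
knn,backward,502,515,27,3260
svm,jump,868,895,36,2880
svm,left,936,954,19,2821
svm,right,885,901,62,2874
svm,forward,493,510,20,3265
svm,backward,498,515,22,3260
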