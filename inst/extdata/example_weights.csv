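# episcore weight file v1
# meta: [{"episcore_id":"CRP_demo","protein_id":"CRP_demo","panel":"synthetic","cohort":"synthetic-demo","n_train":500,"chosen_lambda":0.12,"n_nonzero":4,"note":""},{"episcore_id":"IL6_demo","protein_id":"IL6_demo","panel":"synthetic","cohort":"synthetic-demo","n_train":500,"chosen_lambda":0.2,"n_nonzero":3,"note":""}]
episcore_id,protein_id,panel,cpg,weight
CRP_demo,CRP_demo,synthetic,cg00000029,0.1823
CRP_demo,CRP_demo,synthetic,cg00000108,-0.0741
CRP_demo,CRP_demo,synthetic,cg00000165,0.0329
CRP_demo,CRP_demo,synthetic,cg00000236,-0.2518
IL6_demo,IL6_demo,synthetic,cg00000289,0.1107
IL6_demo,IL6_demo,synthetic,cg00000292,0.0856
IL6_demo,IL6_demo,synthetic,cg00000321,-0.1412
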