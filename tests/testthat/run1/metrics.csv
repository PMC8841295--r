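"item","train_acc","test_acc","precision","sensitivity","specificity","auc","n_features","cost"
"DT",1,0.75,0.666666666666667,1,0.5,0.75,354,0.01
"KT",1,1,1,1,1,1,2,0.01
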