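"threshold","fpr","tpr"
Inf,0,0
0.67314444051115,0,0.5
0.34543393526438,0.5,0.5
0.216146280079824,0.5,1
-0.14819014063924,1,1
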