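"threshold","fpr","tpr"
Inf,0,0
0.077261822110228,0,0.5
0.0308603375282877,0,1
-0.0347951757362384,0.5,1
-0.151335391972422,1,1
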