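"statistic","t","df","p_t","f","p_f"
"max",-2.15495246989308,9.8746471776891,0.0569274247147854,4.64382014749827,0.0565896082987642
"min",0.641632750320382,9.97620033420648,0.535574855930043,0.411692586283698,0.535541128556983
"avg",-2.10014819781418,9.2603056277581,0.064246445536519,4.41062245278213,0.0620617831552008
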