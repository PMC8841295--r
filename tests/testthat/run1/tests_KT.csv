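"statistic","t","df","p_t","f","p_f"
"max",2.31402438399782,6.41010527487533,0.0572077402363341,5.35470884973651,0.0432102886278745
"min",-0.156343613888137,9.24989366540368,0.879121383930621,0.024443325603603,0.878873423991975
"avg",2.49816835491995,5.82606899471415,0.0478188608480507,6.24084512952343,0.0315456817082879
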