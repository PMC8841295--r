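"subject","group","max","min","avg"
"control_01","control",0.00149465357559298,-0.000202254254815726,0.000569620040789277
"control_02","control",0.00177649404506738,-0.000390613567428361,0.00073457679879688
"control_03","control",0.00158254969604155,-0.000319490500348584,0.000579033412759277
"control_04","control",0.00106977722514193,-0.000125126783742955,0.000369083051273394
"control_05","control",0.00133704745800248,-0.000242225789076117,0.000506528142276228
"control_06","control",0.00113243289100688,-0.000177083023750553,0.000408859269148199
"patient_01","patient",0.00127522734168201,-0.000134517332765421,0.000496912525074839
"patient_02","patient",0.0017669826982486,-0.000331705297258168,0.000679844922001051
"patient_03","patient",0.00213383633280575,-0.000364485101894748,0.000770304462411799
"patient_04","patient",0.0019396016409246,-0.000367829311085196,0.00071116010254021
"patient_05","patient",0.0015547210745324,-0.000221086502557821,0.000620461383109
"patient_06","patient",0.0018743429823475,-0.000248795751308231,0.0007359855406425
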