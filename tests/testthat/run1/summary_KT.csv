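"subject","group","max","min","avg"
"control_01","control",1.37176370129649,-0.240884972886622,0.277577471651368
"control_02","control",1.20831718775954,-0.185140264936146,0.243817350532189
"control_03","control",1.30824134528582,-0.341678401425533,0.223823536699169
"control_04","control",1.94532133726153,-0.533070889180229,0.220323325981619
"control_05","control",1.22666565243397,-0.296349604910856,0.220453860439417
"control_06","control",1.27112133307345,-0.463680803276687,0.143828786990755
"patient_01","patient",1.27957890113185,-0.444184017574742,0.188301616279001
"patient_02","patient",1.06533094464297,-0.268505294337229,0.155326341952147
"patient_03","patient",1.01067219197424,-0.243140283916966,0.169671398290522
"patient_04","patient",1.05842972938716,-0.355918223783993,0.175220343001264
"patient_05","patient",1.19297355449356,-0.451872865381142,0.189240134536312
"patient_06","patient",1.03303838924437,-0.233717888961527,0.171795754513745
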