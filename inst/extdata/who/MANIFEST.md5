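ecbaed15e167a6a536cfe134ca2d2c82 who_fgc_ac.csv
eeabb0e7dbfc7ddb86a9081f75dacfe8 who_fgc_birthweight_female.csv
f91fb1b2468053491fa4ee038edc5bbf who_fgc_birthweight_male.csv
dc2b293bbc68658e15fd331cce4b63ae who_fgc_bpd.csv
4c4c7c5e6d4f0adb7a55be3db1dcc078 who_fgc_efw_female.csv
fd9b3b2888c33ea8bc2e0be180e184aa who_fgc_efw_male.csv
6514737d60b85d7066213898a10deb7c who_fgc_efw.csv
3c800133250e045302d2a648ab93e969 who_fgc_fl_bpd.csv
72ef73d4d35624802b4267c7b73698c8 who_fgc_fl_hc.csv
5da807eb54b39ee5e0b9a042871e2d51 who_fgc_fl.csv
ebc24cb714571cf6cca5ef59abde5813 who_fgc_hc.csv
32150493a8e08113e059b00df1c2f6a8 who_fgc_hl.csv
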