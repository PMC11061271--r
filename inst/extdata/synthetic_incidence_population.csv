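"sex","age_lo","age_hi","events","person_years","rate"
"female",0,5,2.09159192986642,1e+05,2.09159192986642e-05
"female",5,10,3.28026911068242,1e+05,3.28026911068242e-05
"female",10,15,5.14448601797023,1e+05,5.14448601797023e-05
"female",15,20,8.0681601100665,1e+05,8.0681601100665e-05
"female",20,25,12.653393815103,1e+05,0.00012653393815103
"female",25,30,19.844471708032,1e+05,0.00019844471708032
"female",30,35,31.1223267943215,1e+05,0.000311223267943215
"female",35,40,48.8095243523415,1e+05,0.000488095243523415
"female",40,45,76.5485718097563,1e+05,0.000765485718097563
"female",45,50,120.05205795111,1e+05,0.0012005205795111
"female",50,55,188.279105377898,1e+05,0.00188279105377898
"female",55,60,295.280415237345,1e+05,0.00295280415237345
"female",60,65,463.091873353325,1e+05,0.00463091873353325
"female",65,70,726.272627981489,1e+05,0.00726272627981489
"female",70,75,1139.02221245134,1e+05,0.0113902221245134
"female",75,80,1786.3424153314,1e+05,0.017863424153314
"female",80,85,2801.54257742218,1e+05,0.0280154257742218
"male",0,5,2.09159192986642,1e+05,2.09159192986642e-05
"male",5,10,3.28026911068242,1e+05,3.28026911068242e-05
"male",10,15,5.14448601797023,1e+05,5.14448601797023e-05
"male",15,20,8.0681601100665,1e+05,8.0681601100665e-05
"male",20,25,12.653393815103,1e+05,0.00012653393815103
"male",25,30,19.844471708032,1e+05,0.00019844471708032
"male",30,35,31.1223267943215,1e+05,0.000311223267943215
"male",35,40,48.8095243523415,1e+05,0.000488095243523415
"male",40,45,76.5485718097563,1e+05,0.000765485718097563
"male",45,50,120.05205795111,1e+05,0.0012005205795111
"male",50,55,188.279105377898,1e+05,0.00188279105377898
"male",55,60,295.280415237345,1e+05,0.00295280415237345
"male",60,65,463.091873353325,1e+05,0.00463091873353325
"male",65,70,726.272627981489,1e+05,0.00726272627981489
"male",70,75,1139.02221245134,1e+05,0.0113902221245134
"male",75,80,1786.3424153314,1e+05,0.017863424153314
"male",80,85,2801.54257742218,1e+05,0.0280154257742218
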