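"sex","age_lo","age_hi","events","person_years","rate"
"female",0,5,63.4609949854113,1e+05,0.000634609949854113
"female",5,10,83.5483465559143,1e+05,0.000835483465559143
"female",10,15,109.993961075332,1e+05,0.00109993961075332
"female",15,20,144.81042380587,1e+05,0.0014481042380587
"female",20,25,190.647364981008,1e+05,0.00190647364981008
"female",25,30,250.99310408018,1e+05,0.0025099310408018
"female",30,35,330.440120701798,1e+05,0.00330440120701798
"female",35,40,435.034555110877,1e+05,0.00435034555110877
"female",40,45,572.736336430859,1e+05,0.00572736336430859
"female",45,50,754.024955522527,1e+05,0.00754024955522527
"female",50,55,992.696983561101,1e+05,0.00992696983561101
"female",55,60,1306.91602970675,1e+05,0.0130691602970675
"female",60,65,1720.59504258514,1e+05,0.0172059504258514
"female",65,70,2265.2161525885,1e+05,0.022652161525885
"female",70,75,2982.22655008837,1e+05,0.0298222655008837
"female",75,80,3926.19273259598,1e+05,0.0392619273259598
"female",80,85,5168.95316790494,1e+05,0.0516895316790494
"male",0,5,63.4609949854113,1e+05,0.000634609949854113
"male",5,10,83.5483465559143,1e+05,0.000835483465559143
"male",10,15,109.993961075332,1e+05,0.00109993961075332
"male",15,20,144.81042380587,1e+05,0.0014481042380587
"male",20,25,190.647364981008,1e+05,0.00190647364981008
"male",25,30,250.99310408018,1e+05,0.0025099310408018
"male",30,35,330.440120701798,1e+05,0.00330440120701798
"male",35,40,435.034555110877,1e+05,0.00435034555110877
"male",40,45,572.736336430859,1e+05,0.00572736336430859
"male",45,50,754.024955522527,1e+05,0.00754024955522527
"male",50,55,992.696983561101,1e+05,0.00992696983561101
"male",55,60,1306.91602970675,1e+05,0.0130691602970675
"male",60,65,1720.59504258514,1e+05,0.0172059504258514
"male",65,70,2265.2161525885,1e+05,0.022652161525885
"male",70,75,2982.22655008837,1e+05,0.0298222655008837
"male",75,80,3926.19273259598,1e+05,0.0392619273259598
"male",80,85,5168.95316790494,1e+05,0.0516895316790494
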