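# synthetic velocity dataset generated from the A3DN_LIKE fixture scheme
# generate_dataset(fixture_scheme("A3DN_LIKE"), noise = noise_options(cv = 0.05, seed = 103))
substrate_uM,modulator_uM,replicate,velocity_nM_per_s,enzyme_nM
5,0,1,0.145984998739053,2
5,0,2,0.152372590116473,2
5,0,3,0.143047773413098,2
10,0,1,0.289165235729318,2
10,0,2,0.264412097249798,2
10,0,3,0.289848648549448,2
15,0,1,0.437742627101407,2
15,0,2,0.445397367752112,2
15,0,3,0.397440026358563,2
20,0,1,0.529389682715733,2
20,0,2,0.514361472832072,2
20,0,3,0.540404549412053,2
25,0,1,0.654000708494518,2
25,0,2,0.733876949419799,2
25,0,3,0.64127244205754,2
50,0,1,1.05231101618437,2
50,0,2,1.1265069904567,2
50,0,3,1.10757467447264,2
100,0,1,1.66702937810046,2
100,0,2,1.7533547926386,2
100,0,3,1.76484439675363,2
5,0.1,1,0.43040448353533,2
5,0.1,2,0.419627170230524,2
5,0.1,3,0.393469702438797,2
10,0.1,1,0.714774625494855,2
10,0.1,2,0.788178365358298,2
10,0.1,3,0.740696543366478,2
15,0.1,1,1.09230811525171,2
15,0.1,2,1.08026552623581,2
15,0.1,3,1.03809411637108,2
20,0.1,1,1.19057125711264,2
20,0.1,2,1.29873912175452,2
20,0.1,3,1.29227278821154,2
25,0.1,1,1.47442185657057,2
25,0.1,2,1.4422553663716,2
25,0.1,3,1.39743811045349,2
50,0.1,1,2.09538181479013,2
50,0.1,2,2.19117355825842,2
50,0.1,3,1.83926722207623,2
100,0.1,1,2.65475232930864,2
100,0.1,2,2.66220745814431,2
100,0.1,3,2.75753394803987,2
5,0.3,1,0.76520958855502,2
5,0.3,2,0.742320144172838,2
5,0.3,3,0.767936702034629,2
10,0.3,1,1.25231336636341,2
10,0.3,2,1.32280426170353,2
10,0.3,3,1.2605476087553,2
15,0.3,1,1.52338770385575,2
15,0.3,2,1.6423142769465,2
15,0.3,3,1.59119265436656,2
20,0.3,1,1.73807435576021,2
20,0.3,2,1.94842108118356,2
20,0.3,3,1.88731828844855,2
25,0.3,1,2.14855728775152,2
25,0.3,2,2.01255778771404,2
25,0.3,3,2.01411538331557,2
50,0.3,1,2.66129129456872,2
50,0.3,2,2.8487259467671,2
50,0.3,3,2.60229819447669,2
100,0.3,1,3.3359601420394,2
100,0.3,2,3.18773929198988,2
100,0.3,3,3.11597743264701,2
5,0.5,1,0.707025823339353,2
5,0.5,2,0.741762327157181,2
5,0.5,3,0.777362721398936,2
10,0.5,1,1.26195272644216,2
10,0.5,2,1.25250121416664,2
10,0.5,3,1.1961522539359,2
15,0.5,1,1.55481958991877,2
15,0.5,2,1.50480696509952,2
15,0.5,3,1.56703629902552,2
20,0.5,1,1.76281698644775,2
20,0.5,2,1.94414840621931,2
20,0.5,3,1.8554028774771,2
25,0.5,1,1.95475011781375,2
25,0.5,2,2.15058438735179,2
25,0.5,3,2.15473774786745,2
50,0.5,1,2.49570505291453,2
50,0.5,2,2.62522441957556,2
50,0.5,3,2.85113691491868,2
100,0.5,1,3.26396985071316,2
100,0.5,2,3.15774593293295,2
100,0.5,3,3.29501474849958,2
5,1,1,0.562379586151133,2
5,1,2,0.623420505461009,2
5,1,3,0.589365953308373,2
10,1,1,0.963058181724763,2
10,1,2,1.04361297165691,2
10,1,3,1.03679957790573,2
15,1,1,1.40167258319629,2
15,1,2,1.30872888825966,2
15,1,3,1.4481038482321,2
20,1,1,1.50099187943943,2
20,1,2,1.56819008691932,2
20,1,3,1.53106028038024,2
25,1,1,1.68755230372455,2
25,1,2,1.96304915709474,2
25,1,3,1.67051010392666,2
50,1,1,2.31358092092812,2
50,1,2,2.51629460378773,2
50,1,3,2.51344240010447,2
100,1,1,2.83106368961353,2
100,1,2,2.66454107626005,2
100,1,3,2.99729712755546,2
5,2,1,0.432159266275832,2
5,2,2,0.403400413124992,2
5,2,3,0.39193803476131,2
10,2,1,0.697372687537668,2
10,2,2,0.80043759092924,2
10,2,3,0.737752471636408,2
15,2,1,1.05862313117056,2
15,2,2,1.03149284831787,2
15,2,3,0.968541084557443,2
20,2,1,1.19277776752448,2
20,2,2,1.24320806317208,2
20,2,3,1.31576693778912,2
25,2,1,1.40150301244156,2
25,2,2,1.41082613030258,2
25,2,3,1.49137062461479,2
50,2,1,1.90757708260753,2
50,2,2,1.99788742800549,2
50,2,3,2.05048840781242,2
100,2,1,2.65888804203383,2
100,2,2,2.51717537729401,2
100,2,3,2.4439653212342,2
5,3,1,0.313425893565551,2
5,3,2,0.308479851433843,2
5,3,3,0.287744544788639,2
10,3,1,0.549192008764379,2
10,3,2,0.600614809310215,2
10,3,3,0.542031323176161,2
15,3,1,0.756145979881134,2
15,3,2,0.716663776935911,2
15,3,3,0.828579964669465,2
20,3,1,0.94484202662658,2
20,3,2,1.03101138546119,2
20,3,3,1.044265188933,2
25,3,1,1.10330128548311,2
25,3,2,1.14642536837821,2
25,3,3,1.19517358046428,2
50,3,1,1.64060260796039,2
50,3,2,1.71962966549663,2
50,3,3,1.71279319308331,2
100,3,1,2.4100037098868,2
100,3,2,2.15785683968801,2
100,3,3,2.36117176102142,2
5,5,1,0.217344499441836,2
5,5,2,0.21226647752579,2
5,5,3,0.206728009632113,2
10,5,1,0.356091800841479,2
10,5,2,0.401798701699223,2
10,5,3,0.360105511551788,2
15,5,1,0.54058694504378,2
15,5,2,0.521073073021974,2
15,5,3,0.544738598677199,2
20,5,1,0.677259420530565,2
20,5,2,0.638155905957297,2
20,5,3,0.664246377900711,2
25,5,1,0.786035661380484,2
25,5,2,0.788749017009702,2
25,5,3,0.764560358392994,2
50,5,1,1.37952471530619,2
50,5,2,1.33173988209867,2
50,5,3,1.35221919009881,2
100,5,1,1.9937413170372,2
100,5,2,2.01099756419391,2
100,5,3,1.99962791367387,2
5,10,1,0.0998128928459128,2
5,10,2,0.108394806629284,2
5,10,3,0.102934279695187,2
10,10,1,0.206837833761294,2
10,10,2,0.212849358695112,2
10,10,3,0.207164547860357,2
15,10,1,0.337904746549225,2
15,10,2,0.312453135388402,2
15,10,3,0.31703626278589,2
20,10,1,0.390009304425837,2
20,10,2,0.423285370338381,2
20,10,3,0.402879126526039,2
25,10,1,0.46409681639508,2
25,10,2,0.476075598273103,2
25,10,3,0.464561515665029,2
50,10,1,0.745187971714975,2
50,10,2,0.830376428987552,2
50,10,3,0.839635572149071,2
100,10,1,1.38333550228805,2
100,10,2,1.31770444980529,2
100,10,3,1.32593728315042,2
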