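# synthetic velocity dataset generated from the Y20S_LIKE fixture scheme
# generate_dataset(fixture_scheme("Y20S_LIKE"), noise = noise_options(cv = 0.05, seed = 102))
substrate_uM,modulator_uM,replicate,velocity_nM_per_s,enzyme_nM
5,0,1,0.269043774802062,2
5,0,2,0.277099029178367,2
5,0,3,0.248596878068444,2
10,0,1,0.527493763590879,2
10,0,2,0.509621498430617,2
10,0,3,0.508713176513037,2
15,0,1,0.683687722196754,2
15,0,2,0.662667481399915,2
15,0,3,0.672349190015601,2
20,0,1,0.875843185968062,2
20,0,2,0.857495798181273,2
20,0,3,0.804343983511081,2
25,0,1,0.893783315357404,2
25,0,2,0.864153100978118,2
25,0,3,0.912211646930057,2
50,0,1,1.31523749109982,2
50,0,2,1.22770906872732,2
50,0,3,1.4494904860469,2
100,0,1,1.56931065236894,2
100,0,2,1.75855752741081,2
100,0,3,1.77752525519359,2
5,0.1,1,0.269314248864314,2
5,0.1,2,0.254223059439347,2
5,0.1,3,0.258820321622036,2
10,0.1,1,0.478497508721811,2
10,0.1,2,0.482677398736369,2
10,0.1,3,0.489196800517225,2
15,0.1,1,0.667076756260563,2
15,0.1,2,0.697450464921261,2
15,0.1,3,0.727874946348329,2
20,0.1,1,0.860182432354977,2
20,0.1,2,0.802687997938911,2
20,0.1,3,0.760990895580111,2
25,0.1,1,0.919008886497955,2
25,0.1,2,0.981727515044545,2
25,0.1,3,1.02423812727901,2
50,0.1,1,1.43752608001927,2
50,0.1,2,1.29986749937709,2
50,0.1,3,1.32599038054214,2
100,0.1,1,1.94818699129725,2
100,0.1,2,1.72003376967583,2
100,0.1,3,1.6897677784521,2
5,0.3,1,0.285397151929442,2
5,0.3,2,0.294935001078434,2
5,0.3,3,0.305053985152786,2
10,0.3,1,0.494200612623867,2
10,0.3,2,0.591321215770184,2
10,0.3,3,0.491009749198344,2
15,0.3,1,0.705295099728007,2
15,0.3,2,0.670825787805422,2
15,0.3,3,0.73845908364292,2
20,0.3,1,0.870100310378544,2
20,0.3,2,0.774570951983006,2
20,0.3,3,0.821867932751761,2
25,0.3,1,0.899684346526855,2
25,0.3,2,0.960039731822876,2
25,0.3,3,0.915876706648336,2
50,0.3,1,1.37502112582516,2
50,0.3,2,1.23664168477457,2
50,0.3,3,1.27600321223359,2
100,0.3,1,1.50304293226895,2
100,0.3,2,1.51145904928565,2
100,0.3,3,1.57329151903239,2
5,0.5,1,0.359244035129359,2
5,0.5,2,0.361427713235507,2
5,0.5,3,0.342945445725117,2
10,0.5,1,0.547278121468964,2
10,0.5,2,0.53123459122314,2
10,0.5,3,0.554314278111028,2
15,0.5,1,0.734649129491247,2
15,0.5,2,0.697748763707811,2
15,0.5,3,0.72683990691242,2
20,0.5,1,0.813061623880462,2
20,0.5,2,0.836632209860773,2
20,0.5,3,0.885630325490171,2
25,0.5,1,1.02551626420397,2
25,0.5,2,0.859051479869707,2
25,0.5,3,0.92498539657397,2
50,0.5,1,1.19986812282934,2
50,0.5,2,1.19516250780992,2
50,0.5,3,1.21119245674317,2
100,0.5,1,1.29390939123115,2
100,0.5,2,1.29517095405822,2
100,0.5,3,1.39966781277953,2
5,1,1,0.365557778032523,2
5,1,2,0.345155617530622,2
5,1,3,0.318722976928122,2
10,1,1,0.56068835161009,2
10,1,2,0.541152330223137,2
10,1,3,0.565009575771277,2
15,1,1,0.683700123847303,2
15,1,2,0.654440123120551,2
15,1,3,0.682850777246324,2
20,1,1,0.755438579115132,2
20,1,2,0.858687878466145,2
20,1,3,0.799365587641527,2
25,1,1,0.830483974943112,2
25,1,2,0.830597650131171,2
25,1,3,0.878572349345723,2
50,1,1,1.1060229503937,2
50,1,2,1.16574810886354,2
50,1,3,1.0013492757426,2
100,1,1,1.06441701100868,2
100,1,2,1.23431338250547,2
100,1,3,1.20851737621571,2
5,2,1,0.279870527152186,2
5,2,2,0.275747480328358,2
5,2,3,0.293371647595422,2
10,2,1,0.478591999658761,2
10,2,2,0.455830408202532,2
10,2,3,0.439828020431171,2
15,2,1,0.578243993606408,2
15,2,2,0.59706926036397,2
15,2,3,0.586594352304667,2
20,2,1,0.632199288995736,2
20,2,2,0.70478902268448,2
20,2,3,0.606368116619318,2
25,2,1,0.719330878001195,2
25,2,2,0.762061566117697,2
25,2,3,0.79721889459099,2
50,2,1,0.960305395208548,2
50,2,2,0.963700270080334,2
50,2,3,0.921536328559559,2
100,2,1,0.967104931106258,2
100,2,2,1.05817685786225,2
100,2,3,1.05142337912751,2
5,3,1,0.224315902482661,2
5,3,2,0.221869790685953,2
5,3,3,0.210903218721145,2
10,3,1,0.335558527128339,2
10,3,2,0.362472293773257,2
10,3,3,0.366124173646592,2
15,3,1,0.462677437013117,2
15,3,2,0.530917601186843,2
15,3,3,0.473216537587335,2
20,3,1,0.604261847210901,2
20,3,2,0.548318904892565,2
20,3,3,0.548536195376122,2
25,3,1,0.647253424788708,2
25,3,2,0.628610796961897,2
25,3,3,0.629527981098661,2
50,3,1,0.839765749516526,2
50,3,2,0.83435623700557,2
50,3,3,0.893655433637242,2
100,3,1,1.03545133752697,2
100,3,2,0.949960395900459,2
100,3,3,1.04509319176149,2
5,5,1,0.155287161081175,2
5,5,2,0.160197221292514,2
5,5,3,0.155479816432497,2
10,5,1,0.251918922712085,2
10,5,2,0.272457981914394,2
10,5,3,0.248876300292374,2
15,5,1,0.382866821794373,2
15,5,2,0.36855769607532,2
15,5,3,0.390799184615327,2
20,5,1,0.465635217894489,2
20,5,2,0.433741310167216,2
20,5,3,0.429012268013886,2
25,5,1,0.533356680503768,2
25,5,2,0.43780241110707,2
25,5,3,0.494250692185728,2
50,5,1,0.728794159292948,2
50,5,2,0.707818289938094,2
50,5,3,0.677812820213649,2
100,5,1,0.918613516353354,2
100,5,2,0.83322569159398,2
100,5,3,0.891496906031565,2
5,10,1,0.0868618209733474,2
5,10,2,0.0789358312233336,2
5,10,3,0.0797146751226011,2
10,10,1,0.172361330309087,2
10,10,2,0.150668695529773,2
10,10,3,0.151800686767967,2
15,10,1,0.238759364815617,2
15,10,2,0.22698862199015,2
15,10,3,0.223498852586901,2
20,10,1,0.27651372844282,2
20,10,2,0.255751194507743,2
20,10,3,0.3058115234125,2
25,10,1,0.345884782972444,2
25,10,2,0.329389304776391,2
25,10,3,0.335337524961371,2
50,10,1,0.554428650808274,2
50,10,2,0.536733626244088,2
50,10,3,0.521638522396587,2
100,10,1,0.66084011527159,2
100,10,2,0.665822771055469,2
100,10,3,0.74459315768902,2
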