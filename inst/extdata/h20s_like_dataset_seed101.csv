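# synthetic velocity dataset generated from the H20S_LIKE fixture scheme
# generate_dataset(fixture_scheme("H20S_LIKE"), noise = noise_options(cv = 0.05, seed = 101))
substrate_uM,modulator_uM,replicate,velocity_nM_per_s,enzyme_nM
5,0,1,0.151340320032607,2
5,0,2,0.158098095137647,2
5,0,3,0.148656379376422,2
10,0,1,0.288779939508471,2
10,0,2,0.29015723786995,2
10,0,3,0.302488768742125,2
15,0,1,0.412379743931856,2
15,0,2,0.397749120496939,2
15,0,3,0.418344569697966,2
20,0,1,0.494422331173001,2
20,0,2,0.513165162392566,2
20,0,3,0.480132594134274,2
25,0,1,0.630231936456369,2
25,0,2,0.545096852933842,2
25,0,3,0.581277552804361,2
50,0,1,0.900302938060641,2
50,0,2,0.870465807988788,2
50,0,3,0.911748551512033,2
100,0,1,1.1988881820309,2
100,0,2,1.12184881764421,2
100,0,3,1.23975759718346,2
5,0.1,1,0.159694071969431,2
5,0.1,2,0.152163757457507,2
5,0.1,3,0.142941239245462,2
10,0.1,1,0.296929921978646,2
10,0.1,2,0.266086358785462,2
10,0.1,3,0.292959752642886,2
15,0.1,1,0.39820807455808,2
15,0.1,2,0.409956795372933,2
15,0.1,3,0.410575651303737,2
20,0.1,1,0.522942140041806,2
20,0.1,2,0.507530749743693,2
20,0.1,3,0.52576842743017,2
25,0.1,1,0.527646676593463,2
25,0.1,2,0.623686179068156,2
25,0.1,3,0.567344246095312,2
50,0.1,1,0.91620359416921,2
50,0.1,2,0.950381876536186,2
50,0.1,3,0.832633630417807,2
100,0.1,1,1.27553860177632,2
100,0.1,2,1.27765882043907,2
100,0.1,3,1.29485991803271,2
5,0.3,1,0.145461559868585,2
5,0.3,2,0.160762600755835,2
5,0.3,3,0.155448857759838,2
10,0.3,1,0.308132769283252,2
10,0.3,2,0.310639864656257,2
10,0.3,3,0.291384055702159,2
15,0.3,1,0.412599696011072,2
15,0.3,2,0.387609406716291,2
15,0.3,3,0.394593338466818,2
20,0.3,1,0.511717209893285,2
20,0.3,2,0.533829342322161,2
20,0.3,3,0.482599232251731,2
25,0.3,1,0.628486768504411,2
25,0.3,2,0.573957555217864,2
25,0.3,3,0.610807258450423,2
50,0.3,1,0.962743119668418,2
50,0.3,2,0.964743955043063,2
50,0.3,3,0.891770479481911,2
100,0.3,1,1.20263652284485,2
100,0.3,2,1.13249129196519,2
100,0.3,3,1.17939093444457,2
5,0.5,1,0.199517313252889,2
5,0.5,2,0.202593996478121,2
5,0.5,3,0.202239164516895,2
10,0.5,1,0.339591764156067,2
10,0.5,2,0.354304571662309,2
10,0.5,3,0.350672492845663,2
15,0.5,1,0.471899935824868,2
15,0.5,2,0.509431831222921,2
15,0.5,3,0.512037964502833,2
20,0.5,1,0.606098560713006,2
20,0.5,2,0.57083371151636,2
20,0.5,3,0.520939594187603,2
25,0.5,1,0.621583418136692,2
25,0.5,2,0.665505900921543,2
25,0.5,3,0.61369989222588,2
50,0.5,1,0.927200202658978,2
50,0.5,2,0.918483471729714,2
50,0.5,3,1.00610659161779,2
100,0.5,1,1.2185076577211,2
100,0.5,2,1.12482965495142,2
100,0.5,3,1.12295351088213,2
5,1,1,0.342787895393089,2
5,1,2,0.384056549963323,2
5,1,3,0.375325776137438,2
10,1,1,0.602431916287929,2
10,1,2,0.584824363866524,2
10,1,3,0.608202906466706,2
15,1,1,0.72335182546408,2
15,1,2,0.677230134015322,2
15,1,3,0.666146955784168,2
20,1,1,0.727431916304886,2
20,1,2,0.765244376452023,2
20,1,3,0.724777210688928,2
25,1,1,0.791144498781209,2
25,1,2,0.864367901261351,2
25,1,3,0.829269705219735,2
50,1,1,0.907357262818397,2
50,1,2,0.958550859113949,2
50,1,3,0.917865352638517,2
100,1,1,1.14337719562591,2
100,1,2,1.09374716679462,2
100,1,3,1.07174138838058,2
5,2,1,0.612231291388526,2
5,2,2,0.622087954595032,2
5,2,3,0.551742677369654,2
10,2,1,0.752887112460355,2
10,2,2,0.835855820534215,2
10,2,3,0.74898305265195,2
15,2,1,0.837344991807392,2
15,2,2,0.832718835842822,2
15,2,3,0.906545208787493,2
20,2,1,0.912046585774465,2
20,2,2,0.84440571214586,2
20,2,3,0.850595356046965,2
25,2,1,0.865963937176347,2
25,2,2,0.876767994085892,2
25,2,3,0.947789737647537,2
50,2,1,0.926718560124997,2
50,2,2,0.921408298955954,2
50,2,3,0.861695844292785,2
100,2,1,0.962113272573695,2
100,2,2,1.00997147036618,2
100,2,3,0.950370960440402,2
5,3,1,0.655205695426622,2
5,3,2,0.670681350500305,2
5,3,3,0.737520032385087,2
10,3,1,0.761672559992966,2
10,3,2,0.780401825605696,2
10,3,3,0.822147744265201,2
15,3,1,0.861770368575228,2
15,3,2,0.798199356386705,2
15,3,3,0.909314473974781,2
20,3,1,0.817137998577726,2
20,3,2,0.97906577377974,2
20,3,3,0.983716121126465,2
25,3,1,0.986968553436348,2
25,3,2,0.901027625435118,2
25,3,3,0.87674343162801,2
50,3,1,0.944170831702213,2
50,3,2,0.892607130430813,2
50,3,3,0.970852692889028,2
100,3,1,1.01575364678748,2
100,3,2,0.968677140983746,2
100,3,3,1.00588499079107,2
5,5,1,0.689544164649589,2
5,5,2,0.697693226272791,2
5,5,3,0.690342419584554,2
10,5,1,0.802623206983888,2
10,5,2,0.838726344587757,2
10,5,3,0.797051627220676,2
15,5,1,0.911092883327243,2
15,5,2,0.861220593599754,2
15,5,3,0.754854011458951,2
20,5,1,0.927628553110744,2
20,5,2,1.00332835751753,2
20,5,3,0.894379284362919,2
25,5,1,0.935617634060527,2
25,5,2,0.925895333307027,2
25,5,3,0.942342724262694,2
50,5,1,0.888938343900702,2
50,5,2,0.884958596435669,2
50,5,3,0.916668153560101,2
100,5,1,1.01898152240626,2
100,5,2,0.94262330067212,2
100,5,3,0.918204339273892,2
5,10,1,0.713231123823369,2
5,10,2,0.647268582579354,2
5,10,3,0.729384589432055,2
10,10,1,0.814690438262394,2
10,10,2,0.862427994197759,2
10,10,3,0.872715897821754,2
15,10,1,0.898766291838593,2
15,10,2,0.935655161010553,2
15,10,3,0.881185998005707,2
20,10,1,0.907066922812978,2
20,10,2,0.965318656137165,2
20,10,3,0.865368795413619,2
25,10,1,0.968091443599176,2
25,10,2,0.882241867317364,2
25,10,3,0.930909877828473,2
50,10,1,0.988102856854436,2
50,10,2,0.987080252736113,2
50,10,3,0.919509483819271,2
100,10,1,0.971313027338513,2
100,10,2,0.969996192446769,2
100,10,3,0.970471683399036,2
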