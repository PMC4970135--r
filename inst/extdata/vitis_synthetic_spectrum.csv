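frequency_hz,real,imag
400000,-0.00285948406092196216,-0.000400516883014235419
405000,-0.00296129524575137896,-0.000406520425670406588
410000,-0.00290869953647844874,-0.000267102496054368282
415000,-0.00293850424489253137,-0.000258064175069856305
420000,-0.00289999204450829386,-0.000292694568937177128
425000,-0.00318050748601769739,-0.000200659953783590442
430000,-0.00320064449443320347,-0.000108878290061980291
435000,-0.00316244877510448840,-0.000028496120738725129
440000,-0.00302623519588751970,0.000129513775798835050
445000,-0.00326285710709893397,0.000223681174428038760
450000,-0.00339184227599584852,0.000336345040086381039
455000,-0.00319211575444902119,0.000340791880151202311
460000,-0.00321131078927139281,0.000495695375036788507
465000,-0.00335303696621822066,0.000396594097869522224
470000,-0.00337727534151936173,0.000566087950296551685
475000,-0.00350267744653853840,0.000734416541481890573
480000,-0.00323543059183023941,0.000786924378618789793
485000,-0.00348293087848774822,0.000869968117483522194
490000,-0.00347996191144046580,0.001024303500035937632
495000,-0.00366687299627193848,0.001228817658083855742
500000,-0.00374159728802860502,0.001209198911024913147
505000,-0.00356653750106914825,0.001430521631612942639
510000,-0.00369297090960579158,0.001476565026352404412
515000,-0.00362134156210044272,0.001701630282626336813
520000,-0.00376568350734938747,0.001823235801057454400
525000,-0.00380846063584574677,0.001825720210629469889
530000,-0.00379160894414699509,0.002137380994058192454
535000,-0.00390633159192121677,0.002342216494649089747
540000,-0.00390400241471897764,0.002431505222559196804
545000,-0.00392035857552361713,0.002783395671855591700
550000,-0.00397641775566833292,0.002976564652817209264
555000,-0.00396717144859612663,0.003149352898364683653
560000,-0.00402354373608548952,0.003458727523308784309
565000,-0.00390467895183815644,0.003821061545546970174
570000,-0.00387071766358654213,0.003954842984372184539
575000,-0.00392087501844155372,0.004248460403690828939
580000,-0.00378196777287117874,0.004714443754863959987
585000,-0.00375542609708028746,0.005074357502213456411
590000,-0.00364625825911853900,0.005477204630527196701
595000,-0.00336535411567439506,0.005783043665065660394
600000,-0.00335700408008870023,0.006295593722538620450
605000,-0.00288667934941665887,0.006515509473015942445
610000,-0.00253197310984614550,0.007063534586438127878
615000,-0.00212275850465688462,0.007610077195836017355
620000,-0.00162581032888704574,0.007979655047647324015
625000,-0.00114702136597353969,0.008327976056353247544
630000,-0.00064691985301004046,0.008752593867815579298
635000,0.00032692928582860455,0.009009315712273613733
640000,0.00112156428429332025,0.009189594634129166426
645000,0.00203593695801135548,0.009128026529571824782
650000,0.00290722643249146772,0.009228125328180330350
655000,0.00394284920151909395,0.008792625308446778629
660000,0.00472818950496679564,0.008439036131400370205
665000,0.00563006299149466146,0.007768596213727290214
670000,0.00644690794178522965,0.007359475420727309633
675000,0.00692992447466168719,0.006506775312388172854
680000,0.00742540623667476817,0.005752492469519192297
685000,0.00753723437262357378,0.004991676742533875111
690000,0.00781992014032399825,0.004152244982932879434
695000,0.00786148022534048467,0.003276681094350491867
700000,0.00768038350753884932,0.002583819029964231836
705000,0.00766799739921345067,0.001928049606095983987
710000,0.00744182113160093191,0.001248596331263779682
715000,0.00734468650579193309,0.000779112524346816716
720000,0.00700792969718851480,0.000368827193593080434
725000,0.00675391233590151140,0.000036170306918664529
730000,0.00644429932575757251,-0.000343771982764503551
735000,0.00619771942784516899,-0.000885516287639636756
740000,0.00593689711131033596,-0.000960635368606782840
745000,0.00575792102466165211,-0.001181586436207505975
750000,0.00542968981655461962,-0.001458650044461032649
755000,0.00502814038413319526,-0.001711568572967424925
760000,0.00499272669137859875,-0.001935084513692837726
765000,0.00468102730366382058,-0.001960825100133188007
770000,0.00433802525129955464,-0.002058137040631418616
775000,0.00417598908997322913,-0.002161954057781455621
780000,0.00399069630980475494,-0.002288066521836046221
785000,0.00383567649578386806,-0.002340396398441416809
790000,0.00358697476864603933,-0.002410496408640255567
795000,0.00344233741464374660,-0.002354984871020250788
800000,0.00338994531865419646,-0.002447996737516812838
805000,0.00319672954863817107,-0.002480487603117788320
810000,0.00298091686810214238,-0.002590298875241682508
815000,0.00273710563679695684,-0.002644374564168093435
820000,0.00273145947668665141,-0.002681368995383228478
825000,0.00259082564729583775,-0.002665628420695724532
830000,0.00247379681288644078,-0.002701158056259007380
835000,0.00220728123259892684,-0.002703578935814565046
840000,0.00234276127776907733,-0.002862831838849844331
845000,0.00207021087791999740,-0.002680572482491657728
850000,0.00201949406198813916,-0.002748543112694507799
855000,0.00183387680339763348,-0.002710795635146009356
860000,0.00173390471209732217,-0.002685385643673499686
865000,0.00169115896954325222,-0.002798480681136604475
870000,0.00159430473859239379,-0.002766571559646330801
875000,0.00143087053045508816,-0.002685801076472457520
880000,0.00138929225129518549,-0.002610551385226956688
885000,0.00131072917909575868,-0.002744526405260176282
890000,0.00132048691201650556,-0.002683441677599881104
895000,0.00113186716827033402,-0.002800500384475801061
900000,0.00096299412867167607,-0.002602761014816741460
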