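pulse_1,pulse_2,pulse_3,pulse_4,pulse_5,pulse_6,pulse_7,pulse_8,pulse_9,pulse_10
48.635570141895,23.9387752197249,44.9060447379105,37.190402210852,44.5412837658404,66.540824726536,20.3758319151442,31.7491288222413,12.63695250367,14.6734859332738
57.5540745344222,18.551936820811,34.0816715288945,49.5439374338428,23.4726730774936,-4.10764499780351,39.6666963761758,27.9620591856817,30.5113373483895,33.9926081147442
86.2547284686627,-1.98988084126916,27.4386678911217,6.60309001095671,12.16187035345,30.3561481370179,12.5319471325031,-0.0789881575027126,9.03962333527893,14.1243325655733
46.545586456879,11.0607605305521,19.8375692536059,17.2518275700507,14.0303050905478,32.5319654488793,24.542872505827,-1.90470905321993,27.8200309755624,16.4934840996855
56.1819996140903,34.571458177714,27.1225796594063,28.032119505373,48.4971748832838,44.0455345836706,59.5022750059038,11.2909280775381,45.9664897415543,0.506750405330366
92.4593335681606,9.66088895273853,4.78494775866551,45.393081353427,9.08127877670231,20.9268215460607,16.5398225803063,41.9690118161671,45.5397820969824,12.8532938848712
39.7633923583866,22.7128175441165,12.099355705958,13.3103157907668,19.920033298313,47.3191440718168,-0.241909562215532,39.8036792946702,11.9588042053091,41.8533135239414
45.8890524450893,47.8952387987516,6.89511679798143,60.6605391041103,28.4246979910793,13.596675761781,6.94333167357527,46.6017585481855,34.1798694984395,72.3177619052988
74.7447364698442,60.2342765327702,59.4527831383367,10.7109787437058,47.9269430782485,49.8837309417639,46.1927459322522,67.981432320719,44.0235828716762,30.6144982985162
62.6298374619646,15.418408907948,9.14816900942424,53.2356825049835,30.8379877470841,18.5572778077077,24.1697360539427,8.99546990538342,17.209728886922,47.5398503788829
34.858108191206,43.9408433372801,84.833288936918,46.0654816141714,22.9430162366494,31.6405098679624,19.9472014737957,23.9911256189586,10.4698132073885,42.6823095705197
46.5140585523207,17.5220093860792,30.866644335522,31.4227158048442,17.060653275359,29.6475490265084,15.9282397580679,19.5644694576175,-0.82159244272322,24.5238121147352
22.7484350480364,79.7056449151378,21.9079915880701,16.2533192168474,29.0710669364576,6.13950504994186,10.0067365498865,14.6409396591414,-0.122955609445138,22.9952565422603
50.4600295081426,38.8557560670169,45.1313501874089,15.0790675191811,26.8567632824155,18.6473875324449,17.894136959773,32.4307415825753,17.0467344739852,1.13546534444961
27.4966300646183,39.195708283554,35.2351689105119,24.4586478821336,7.28491837168118,17.2240629946537,7.54165149507527,12.0176643294648,25.9621186096737,14.9345958331071
59.0326966289097,30.6190570452185,-0.24859042455021,11.1593162552361,32.8479494768451,16.4626673381327,10.7023527164184,15.4793734381902,14.8834849963295,5.729240193903
8.8907372126585,42.2216867968821,28.9786607691198,11.622982805979,21.8457846487509,13.1231606078252,33.583099881932,61.7286323141077,-2.15154796224596,27.5346220896548
25.4671568268194,12.8612336041179,15.2213296670655,11.8668153301396,7.75453249447652,2.95842275138593,0.113286109178729,17.1323517761669,19.198737001656,23.6722802358483
70.894437459873,14.9699418206532,55.4112489976246,23.4220463987767,31.3495755012815,49.709034325249,10.2688891839825,9.95770857296717,1.96621923878025,20.3374060971518
40.0449235560601,18.1639584718753,25.008485997992,35.7446523115781,33.7762202321577,59.9802138922304,14.6933856806745,9.73192518958835,22.212395826223,7.41073253758541
61.6665874466427,38.2869617874623,28.3099601311749,53.278217759669,47.8639825666312,21.4045063548756,-0.620969993985142,15.7008024822206,-0.781417469122486,22.368107022606
46.4424295143195,23.8546386235452,29.0367998399503,21.6995470469935,30.5002011974037,5.91106815225625,33.7565892150753,-0.303504500498604,29.4899273455064,31.0156307299751
30.7710498531281,-3.14158232960557,-3.59215155488314,16.3371317790973,16.6902039200939,-1.54917440867479,52.0038961412847,29.6058318913621,16.7343918232678,40.0474394381616
21.3016815364411,20.5077728580929,16.2723001207663,1.14896759446074,-2.83612088197752,38.0235269990126,26.4606142848102,10.9656050255243,37.9040058817396,-1.99616803394195
35.1701775376975,49.6117983369963,17.5676848633927,7.23344222361683,-0.116538775300512,0.647236707441527,29.3293345149438,0.95751324036001,15.7675478533662,35.0855726993092
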