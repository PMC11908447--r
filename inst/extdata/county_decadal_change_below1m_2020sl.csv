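county_id,state,change_1990s,change_2000s,change_2010s,printed_total
Cameron,LA,-61,-2255,-340,-2656
St. Bernard,LA,319,-25638,6963,-18356
Hyde,NC,-170,-238,-708,-1117
Orleans,LA,-11361,-130806,41188,-100979
Tyrrell,NC,257,257,-1073,-560
Plaquemines,LA,1076,-3690,574,-2040
St. Mary,LA,-1997,1172,-1889,-2713
Somerset,MD,-213,-419,-395,-1028
Pamlico,NC,-129,-109,-170,-408
Cape May,NJ,840,-3025,-634,-2819
Beaufort,NC,-502,-193,-441,-1136
Jefferson,TX,-2225,-3182,-986,-6393
Accomack,VA,455,-1137,-20,-703
Dorchester,MD,-3,-335,-305,-642
Jefferson,LA,5644,-21027,6929,-8454
Salem,NJ,-631,-548,-41,-1220
Vermilion,LA,-174,-501,-258,-933
Mathews,VA,173,-227,-87,-141
Dixie,FL,-53,-61,-58,-171
Gloucester,VA,-147,-267,-1,-416
Terrebonne,LA,-241,1991,-2773,-1024
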