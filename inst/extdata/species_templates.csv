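"species","compound","mean","value_kind","hot_spot","cv_scale"
"orange","hexamethyl-O-quercetagetin",1.2,"concentration",1,2
"orange","sinensetin",1.1,"concentration",1,1
"orange","tetramethyl-O-scutellarein",0.9,"concentration",1,2.5
"orange","3,5,6,7,8,3',4'-heptamethoxyflavone",0.8,"concentration",1,2
"orange","nobiletin",0.15,"concentration",0,3
"orange","isosinensetin",0.02,"concentration",0,1
"orange","tangeretin",0.015,"concentration",0,1
"orange","tetramethyl-O-isoscutellarein",0.06,"concentration",0,3
"orange","5-demethylnobiletin",0.05,"concentration",0,3
"orange","5-demethyltangeretin",0.005,"concentration",0,4
"orange","scopoletin",0.1,"concentration",0,1
"orange","candidate I",50,"area",0,1
"orange","candidate V",80,"area",1,1
"orange","candidate VI",60,"area",1,1
"mandarin","3,5,6,7,8,3',4'-heptamethoxyflavone",1.6,"concentration",1,2
"mandarin","nobiletin",1.5,"concentration",1,3
"mandarin","tangeretin",1.4,"concentration",1,1
"mandarin","5-demethylnobiletin",0.8,"concentration",1,3
"mandarin","isosinensetin",0.9,"concentration",1,1
"mandarin","tetramethyl-O-isoscutellarein",0.7,"concentration",1,3
"mandarin","5-demethyltangeretin",0.6,"concentration",1,4
"mandarin","sinensetin",0.08,"concentration",0,1
"mandarin","tetramethyl-O-scutellarein",0.3,"concentration",0,2
"mandarin","hexamethyl-O-quercetagetin",0.1,"concentration",0,1
"mandarin","scopoletin",0.15,"concentration",0,1
"mandarin","candidate I",60,"area",0,1
"grapefruit","meranzin hydrate",1.5,"concentration",0,1
"grapefruit","bergaptol",0.3,"concentration",0,1
"grapefruit","bergapten",2.5,"concentration",0,1
"grapefruit","meranzin",0.5,"concentration",0,1
"grapefruit","isomeranzin",0.2,"concentration",0,1
"grapefruit","auraptenol",0.5,"concentration",0,1
"grapefruit","citropten",0.3,"concentration",0,1
"grapefruit","oxypeucedanin",2,"concentration",0,1
"grapefruit","oxypeucedanin hydrate",0.8,"concentration",0,1
"grapefruit","marmin",1.2,"concentration",0,1
"grapefruit","6',7'-dihydroxy-bergamottin",0.5,"concentration",0,1
"grapefruit","imperatorin",0.8,"concentration",0,1
"grapefruit","osthole",1.2,"concentration",1,1
"grapefruit","isoimperatorin",0.9,"concentration",0,1
"grapefruit","6',7'-epoxy-bergamottin",0.3,"concentration",0,1
"grapefruit","8-geranyloxy-psoralen",0.4,"concentration",0,1
"grapefruit","auraptene",1.5,"concentration",0,1
"grapefruit","bergamottin",5,"concentration",1,1
"grapefruit","5-geranoxy-7-methoxycoumarin",0.6,"concentration",0,1
"grapefruit","phellopterin",0.5,"concentration",0,1
"grapefruit","byakangelicin",0.4,"concentration",0,1
"grapefruit","byakangelicol",0.3,"concentration",0,1
"grapefruit","heraclenin",0.3,"concentration",0,1
"grapefruit","heraclenol",0.3,"concentration",0,1
"grapefruit","3,5,6,7,8,3',4'-heptamethoxyflavone",1,"concentration",1,1
"grapefruit","nobiletin",0.3,"concentration",0,1
"grapefruit","tangeretin",0.25,"concentration",0,1
"grapefruit","tetramethyl-O-scutellarein",0.3,"concentration",0,1
"grapefruit","5-demethylnobiletin",0.2,"concentration",0,1
"grapefruit","tetramethyl-O-isoscutellarein",0.2,"concentration",0,1
"grapefruit","sinensetin",0.25,"concentration",0,1
"grapefruit","scopoletin",0.1,"concentration",0,1
"grapefruit","candidate XI",70,"area",1,1
"grapefruit","candidate I",55,"area",0,1
"pomelo-SG","meranzin",4,"concentration",1,1
"pomelo-SG","meranzin hydrate",2,"concentration",0,1
"pomelo-SG","3,5,6,7,8,3',4'-heptamethoxyflavone",0.06,"concentration",0,1
"pomelo-SG","osthole",0.1,"concentration",0,1
"pomelo-SG","6',7'-epoxy-bergamottin",2.5,"concentration",1,1
"pomelo-SG","bergamottin",0.5,"concentration",0,1
"pomelo-SG","scopoletin",0.05,"concentration",0,1
"pomelo-SG","bergaptol",2,"concentration",0,1
"pomelo-SG","isomeranzin",1.2,"concentration",0,1
"pomelo-SG","6',7'-dihydroxy-bergamottin",3,"concentration",0,1
"pomelo-SG","bergapten",2,"concentration",0,1
"pomelo-SG","oxypeucedanin",1.5,"concentration",0,1
"pomelo-SG","marmin",1,"concentration",0,1
"pomelo-SG","auraptene",2,"concentration",1,1
"pomelo-SG","imperatorin",0.3,"concentration",0,1
"pomelo-SG","isoimperatorin",0.4,"concentration",0,1
"pomelo-SG","tetramethyl-O-scutellarein",0.08,"concentration",0,1
"pomelo-SG","tangeretin",0.05,"concentration",0,1
"pomelo-SG","5-demethylnobiletin",0.04,"concentration",0,1
"pomelo-SG","candidate I",50,"area",0,1
"pomelo-WG","bergaptol",2.5,"concentration",1,1
"pomelo-WG","isomeranzin",1.5,"concentration",1,1
"pomelo-WG","6',7'-dihydroxy-bergamottin",3.5,"concentration",1,1
"pomelo-WG","meranzin",0.3,"concentration",0,1
"pomelo-WG","meranzin hydrate",2,"concentration",0,1
"pomelo-WG","bergapten",2,"concentration",0,1
"pomelo-WG","oxypeucedanin",1.2,"concentration",0,1
"pomelo-WG","marmin",1,"concentration",0,1
"pomelo-WG","auraptene",2.5,"concentration",1,1
"pomelo-WG","bergamottin",4,"concentration",1,1
"pomelo-WG","6',7'-epoxy-bergamottin",0.2,"concentration",0,1
"pomelo-WG","osthole",0.9,"concentration",0,1
"pomelo-WG","imperatorin",0.5,"concentration",0,1
"pomelo-WG","isoimperatorin",0.6,"concentration",0,1
"pomelo-WG","candidate I",45,"area",0,1
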