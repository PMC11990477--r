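"compound","opt","series_ids","descriptor"
"Ethyl acetate",0.02,"1;2;4","chemical/fruity/ripe fruit/green"
"Butyl acetate",0.1,"2","fruity/ripe fruit"
"Isoamyl acetate",0.5,"2","fruity/ripe fruit"
"(Z)-3-Hexenyl acetate",1,"2;4","fruity/ripe fruit/green"
"Hexyl acetate",5,"2;3","fruity/ripe fruit/green fruit"
"Octyl acetate",20,"5;11","floral/waxy"
"Ethyl phenylacetate",0.02,"5;10","floral/honey"
"2-Phenylethyl acetate",0.1,"5;10","floral/honey"
"Geranyl acetate",0.5,"5","floral"
"Ethyl lactate",1,"2","fruity/ripe fruit"
"Ethyl isobutyrate",5,"2","fruity/ripe fruit"
"Ethyl butyrate",20,"2","fruity/ripe fruit"
"Ethyl 2-methylbutyrate",0.02,"2","fruity/ripe fruit"
"Ethyl 3-methylbutyrate",0.1,"2;3","fruity/ripe fruit/green fruit"
"Diethyl succinate",0.5,"2","fruity/ripe fruit"
"Ethyl hexanoate",1,"2;3","fruity/ripe fruit/green fruit"
"Ethyl heptanoate",5,"2;3","fruity/ripe fruit/green fruit"
"Ethyl octanoate",20,"2;11","fruity/ripe fruit/waxy"
"Ethyl decanoate",0.02,"2;11","fruity/ripe fruit/waxy"
"Ethyl dodecanoate",0.1,"11","waxy"
"Ethyl tetradecanoate",0.5,"5;6","floral/creamy"
"Ethyl hexadecanoate",1,"2;6;11","fruity/ripe fruit/creamy/waxy"
"Cis-3-Hexenyl butyrate",5,"4","green"
"2-Phenylethyl butanoate",20,"5","floral"
"E-Methyldihydrojasmonate",0.02,"5","floral"
"Methanol",0.1,"1","chemical"
"1-Propanol",0.5,"1;4","chemical/green"
"Isobutanol",1,"1","chemical"
"2-Methyl-1-butanol",5,"1","chemical"
"3-Methyl-1-butanol",20,"1","chemical"
"2-Phenylethanol",0.02,"5","floral"
"Hexanol",0.1,"4","green"
"2-Ethyl-1-hexanol",0.5,"7","citrus"
"Dodecanol",1,"11","waxy"
"2-Methoxy-4-vinylphenol",5,"9","toasty/smoky"
"gamma-Butyrolactone",20,"6","creamy"
"gamma-Crotonolactone",0.02,"6","creamy"
"gamma-Nonalactone",0.1,"6;2","creamy/fruity/ripe fruit"
"beta-Damascenone",0.5,"5;8","floral/herbaceous"
"Acetaldehyde",1,"1;2","chemical/fruity/ripe fruit"
"1,1-Diethoxyethane",5,"1;4","chemical/green"
"Acetoin",20,"6","creamy"
"Hexanal",0.02,"4","green"
"Furfural",0.1,"1;9","chemical/toasty/smoky"
"Benzaldehyde",0.5,"2","fruity/ripe fruit"
"Octanal",1,"7","citrus"
"Nonanal",5,"7","citrus"
"2-Phenylacetaldehyde",20,"4;10","green/honey"
"Decanal",0.02,"8;11","herbaceous/waxy"
"Limonene",0.1,"1;7","chemical/citrus"
"E-Geranyl acetone",0.5,"5","floral"
"Z-Geranyl acetone",1,"5","floral"
"Nerolidol",5,"4;5","green/floral"
"Farnesol",20,"5","floral"
"2,3-Butanediol levo",0.02,"2;6","fruity/ripe fruit/creamy"
"2,3-Butanediol meso",0.1,"2;6","fruity/ripe fruit/creamy"
"2-Pentylfuran",0.5,"3","green fruit"
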