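"state","passage_date","rtp_provider","provider_breadth","education"
"AK","2011-07-01","specified","multiple","both"
"AL","2011-07-01","specified","physicians_only","both"
"AR","2013-07-01","not_specified","not_applicable","both"
"AZ","2011-07-01","specified","multiple","both"
"CA","2011-07-01","not_specified","not_applicable","either"
"CO","2011-07-01","specified","multiple","either"
"CT","2010-07-01","specified","multiple","either"
"DC","2011-07-01","not_specified","not_applicable","either"
"DE","2011-07-01","specified","physicians_only","both"
"FL","2012-07-01","not_specified","not_applicable","both"
"GA","2013-07-01","specified","multiple","either"
"HI","2012-07-01","specified","multiple","both"
"IA","2011-07-01","specified","multiple","both"
"ID","2010-07-01","specified","multiple","both"
"IL","2011-07-01","not_specified","not_applicable","both"
"IN","2011-07-01","not_specified","not_applicable","both"
"KS","2011-07-01","specified","multiple","both"
"KY","2012-07-01","not_specified","not_applicable","both"
"LA","2011-07-01","specified","multiple","both"
"MA","2010-07-01","specified","multiple","both"
"MD","2011-07-01","not_specified","not_applicable","both"
"ME","2011-07-01","specified","multiple","both"
"MI","2012-07-01","not_specified","not_applicable","both"
"MN","2011-07-01","specified","multiple","either"
"MO","2011-07-01","not_specified","not_applicable","either"
"MS","2014-07-01","specified","multiple","either"
"MT","2013-07-01","not_specified","not_applicable","both"
"NC","2011-07-01","specified","multiple","both"
"ND","2011-07-01","not_specified","not_applicable","both"
"NE","2011-07-01","specified","multiple","either"
"NH","2012-07-01","not_specified","not_applicable","both"
"NJ","2010-07-01","specified","multiple","both"
"NM","2010-07-01","specified","multiple","both"
"NV","2011-07-01","specified","multiple","either"
"NY","2011-07-01","specified","physicians_only","both"
"OH","2012-07-01","specified","physicians_only","both"
"OK","2010-07-01","not_specified","not_applicable","both"
"OR","2009-07-01","not_specified","not_applicable","either"
"PA","2011-07-01","not_specified","not_applicable","both"
"RI","2010-07-01","specified","physicians_only","both"
"SC","2013-07-01","specified","multiple","both"
"SD","2011-07-01","not_specified","not_applicable","both"
"TN","2013-07-01","specified","physicians_only","both"
"TX","2011-07-01","specified","physicians_only","both"
"UT","2011-07-01","not_specified","not_applicable","both"
"VA","2010-07-01","not_specified","not_applicable","both"
"VT","2011-07-01","not_specified","not_applicable","both"
"WA","2009-07-01","not_specified","not_applicable","both"
"WI","2012-07-01","not_specified","not_applicable","both"
"WV","2013-07-01","not_specified","not_applicable","both"
"WY","2011-07-01","not_specified","not_applicable","both"
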