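rrna,mito,hostsymb,nr,expected
yes,yes,lt,metazoan,rRNA
yes,yes,lt,nonmetazoan,rRNA
yes,yes,lt,absent,rRNA
yes,yes,gt,metazoan,rRNA
yes,yes,gt,nonmetazoan,rRNA
yes,yes,gt,absent,rRNA
yes,yes,tie,metazoan,rRNA
yes,yes,tie,nonmetazoan,rRNA
yes,yes,tie,absent,rRNA
yes,yes,host_only,metazoan,rRNA
yes,yes,host_only,nonmetazoan,rRNA
yes,yes,host_only,absent,rRNA
yes,yes,symb_only,metazoan,rRNA
yes,yes,symb_only,nonmetazoan,rRNA
yes,yes,symb_only,absent,rRNA
yes,yes,neither,metazoan,rRNA
yes,yes,neither,nonmetazoan,rRNA
yes,yes,neither,absent,rRNA
yes,no,lt,metazoan,rRNA
yes,no,lt,nonmetazoan,rRNA
yes,no,lt,absent,rRNA
yes,no,gt,metazoan,rRNA
yes,no,gt,nonmetazoan,rRNA
yes,no,gt,absent,rRNA
yes,no,tie,metazoan,rRNA
yes,no,tie,nonmetazoan,rRNA
yes,no,tie,absent,rRNA
yes,no,host_only,metazoan,rRNA
yes,no,host_only,nonmetazoan,rRNA
yes,no,host_only,absent,rRNA
yes,no,symb_only,metazoan,rRNA
yes,no,symb_only,nonmetazoan,rRNA
yes,no,symb_only,absent,rRNA
yes,no,neither,metazoan,rRNA
yes,no,neither,nonmetazoan,rRNA
yes,no,neither,absent,rRNA
no,yes,lt,metazoan,mtDNA
no,yes,lt,nonmetazoan,mtDNA
no,yes,lt,absent,mtDNA
no,yes,gt,metazoan,mtDNA
no,yes,gt,nonmetazoan,mtDNA
no,yes,gt,absent,mtDNA
no,yes,tie,metazoan,mtDNA
no,yes,tie,nonmetazoan,mtDNA
no,yes,tie,absent,mtDNA
no,yes,host_only,metazoan,mtDNA
no,yes,host_only,nonmetazoan,mtDNA
no,yes,host_only,absent,mtDNA
no,yes,symb_only,metazoan,mtDNA
no,yes,symb_only,nonmetazoan,mtDNA
no,yes,symb_only,absent,mtDNA
no,yes,neither,metazoan,mtDNA
no,yes,neither,nonmetazoan,mtDNA
no,yes,neither,absent,mtDNA
no,no,lt,metazoan,other_taxa
no,no,lt,nonmetazoan,dinoflagellate
no,no,lt,absent,dinoflagellate
no,no,gt,metazoan,metazoan
no,no,gt,nonmetazoan,other_taxa
no,no,gt,absent,metazoan
no,no,tie,metazoan,other_taxa
no,no,tie,nonmetazoan,other_taxa
no,no,tie,absent,other_taxa
no,no,host_only,metazoan,metazoan
no,no,host_only,nonmetazoan,other_taxa
no,no,host_only,absent,metazoan
no,no,symb_only,metazoan,other_taxa
no,no,symb_only,nonmetazoan,dinoflagellate
no,no,symb_only,absent,dinoflagellate
no,no,neither,metazoan,metazoan
no,no,neither,nonmetazoan,other_taxa
no,no,neither,absent,no_match
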