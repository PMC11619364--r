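category	pattern
FUNCTION_UNKNOWN	hypothetical protein
FUNCTION_UNKNOWN	\bDUF\d*
FUNCTION_UNKNOWN	domain of unknown function
FUNCTION_UNKNOWN	^nan$
FUNCTION_UNKNOWN	uncharacteri[sz]ed
FUNCTION_UNKNOWN	unknown function
TRANSPOSON_ASSOCIATED	transposase
TRANSPOSON_ASSOCIATED	transposon
TRANSPOSON_ASSOCIATED	integrase
TRANSPOSON_ASSOCIATED	insertion sequence
TRANSPOSON_ASSOCIATED	\bIS\d+
TRANSPOSON_ASSOCIATED	resolvase
PLASMID_BACKBONE	conjuga
PLASMID_BACKBONE	\btra[A-Z]\b
PLASMID_BACKBONE	\btrb[A-Z]\b
PLASMID_BACKBONE	type IV secretion
PLASMID_BACKBONE	relaxase
PLASMID_BACKBONE	mobili[sz]ation
PLASMID_BACKBONE	\bmob[A-Z]\b
PLASMID_BACKBONE	replication initiat
PLASMID_BACKBONE	replication control
PLASMID_BACKBONE	replication protein
PLASMID_BACKBONE	\brep[A-Z]\b
PLASMID_BACKBONE	copy number
PLASMID_BACKBONE	\bcop[A-Z]\b
PLASMID_BACKBONE	plasmid replication
PLASMID_BACKBONE	partition
PLASMID_BACKBONE	\bpar[A-Z]\b
PLASMID_BACKBONE	plasmid stabili[sz]ation
PLASMID_BACKBONE	toxin-antitoxin
PLASMID_BACKBONE	antitoxin
PLASMID_BACKBONE	\btoxin\b
PLASMID_BACKBONE	addiction
PLASMID_BACKBONE	post-?segregational killing
POTENTIAL_BACKBONE	methyltransferase
POTENTIAL_BACKBONE	methylation
POTENTIAL_BACKBONE	methylase
POTENTIAL_BACKBONE	restriction
POTENTIAL_BACKBONE	anti-restriction
POTENTIAL_BACKBONE	endonuclease
POTENTIAL_BACKBONE	exonuclease
POTENTIAL_BACKBONE	\bnuclease\b
POTENTIAL_BACKBONE	helicase
POTENTIAL_BACKBONE	topoisomerase
POTENTIAL_BACKBONE	primase
POTENTIAL_BACKBONE	recombinase
POTENTIAL_BACKBONE	DNA[- ]binding
POTENTIAL_BACKBONE	single-strand(ed)? DNA
POTENTIAL_BACKBONE	\bssb\b
POTENTIAL_BACKBONE	DNA repair
POTENTIAL_BACKBONE	DNA process
GENERAL_FUNCTIONAL	ATPase
GENERAL_FUNCTIONAL	ribosom
GENERAL_FUNCTIONAL	phage
GENERAL_FUNCTIONAL	metabol
GENERAL_FUNCTIONAL	dehydrogenase
GENERAL_FUNCTIONAL	kinase
GENERAL_FUNCTIONAL	transport
GENERAL_FUNCTIONAL	permease
GENERAL_FUNCTIONAL	reductase
GENERAL_FUNCTIONAL	synthase
GENERAL_FUNCTIONAL	synthetase
GENERAL_FUNCTIONAL	transferase
GENERAL_FUNCTIONAL	regulator
GENERAL_FUNCTIONAL	membrane protein
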