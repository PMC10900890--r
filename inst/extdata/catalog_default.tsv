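#version: cobatlas-default-1.0
family_id	profile_accession	pathway_section	display_name
hemA	TIGR01202	precursor	glutamyl-tRNA reductase
hemB	PF00490	precursor	delta-aminolevulinic acid dehydratase
hemC	PF01379	precursor	porphobilinogen deaminase
hemD	PF02602	precursor	uroporphyrinogen-III synthase
cobA_cysG	TIGR01469	precursor	uroporphyrinogen-III C-methyltransferase
cobG	TIGR02469	ring_aerobic	precorrin-3B synthase
cobJ	TIGR02467	ring_aerobic	precorrin-3B C17-methyltransferase
cobM	TIGR01271	ring_aerobic	precorrin-4 C11-methyltransferase
cobF	TIGR02460	ring_aerobic	precorrin-6A synthase
cobK	TIGR02471	ring_aerobic	precorrin-6X reductase
cobN	TIGR02257	ring_aerobic	aerobic cobaltochelatase CobN subunit
cobS_chel	TIGR02459	ring_aerobic	aerobic cobaltochelatase CobS subunit
cbiK	PF06180	ring_anaerobic	anaerobic cobalt chelatase CbiK
cbiL	TIGR01466	ring_anaerobic	precorrin-2 C20-methyltransferase
cbiH	TIGR01021	ring_anaerobic	precorrin-3B C17-methyltransferase (anaerobic)
cbiF	TIGR00712	ring_anaerobic	precorrin-4 C11-methyltransferase (anaerobic)
cbiD	TIGR00379	ring_anaerobic	cobalt-precorrin-5B C1-methyltransferase
cbiJ	TIGR02470	ring_anaerobic	cobalt-precorrin-6X reductase
cbiG	TIGR01022	ring_anaerobic	cobalt-precorrin-5A hydrolase
cobB_cbiA	TIGR00379b	ring_shared	cobyrinate a,c-diamide synthase (shared profile)
cobH_cbiC	TIGR01679	ring_shared	precorrin-8X methylmutase (shared profile)
cobL_cbiET	TIGR02468	ring_shared	precorrin-6Y C5,15-methyltransferase (shared profile)
cobQ_cbiP	TIGR00313	ring_shared	cobyric acid synthase (shared profile)
cobD_cbiB	TIGR00380	loop	adenosylcobinamide-phosphate synthase
cobU	TIGR00708	loop	adenosylcobinamide kinase / guanylyltransferase
cobS	TIGR00317	loop	cobalamin-5'-phosphate synthase
cobT	TIGR03160	loop	nicotinate-nucleotide--DMB phosphoribosyltransferase
cobC	PF00702c	loop	alpha-ribazole phosphatase
bluB	TIGR02476	loop	5,6-dimethylbenzimidazole synthase
btuB	TIGR01779	transport_salvage	cobalamin outer-membrane transporter
btuF	PF01497	transport_salvage	cobalamin ABC transporter substrate-binding protein
btuC	TIGR01295	transport_salvage	cobalamin ABC transporter permease
btuD	PF00005b	transport_salvage	cobalamin ABC transporter ATPase
metH	TIGR02082	user_dependent	cobalamin-dependent methionine synthase
nrdJ	TIGR02504	user_dependent	class II ribonucleotide reductase
mutA	TIGR00641	user_dependent	methylmalonyl-CoA mutase
icmF	TIGR00642	user_dependent	isobutyryl-CoA mutase
glmE	TIGR03319	user_dependent	glutamate mutase epsilon subunit
mgm	TIGR03320	user_dependent	2-methyleneglutarate mutase
oraE	TIGR03321	user_dependent	D-ornithine aminomutase
kamD	TIGR03322	user_dependent	lysine-5,6-aminomutase
eutB	TIGR02528	user_dependent	ethanolamine ammonia-lyase large subunit
pduC	TIGR02522	user_dependent	propanediol/glycerol dehydratase large subunit
queG	TIGR00276	user_dependent	epoxyqueuosine reductase
rdhA	PF13486	user_dependent	reductive dehalogenase
mtaC	TIGR02370	user_dependent	methanol corrinoid methyltransferase subunit
COG0012	COG0012	single_copy	ribosome-binding ATPase YchF
COG0016	COG0016	single_copy	phenylalanyl-tRNA synthetase alpha subunit
COG0018	COG0018	single_copy	arginyl-tRNA synthetase
COG0048	COG0048	single_copy	ribosomal protein S12
COG0049	COG0049	single_copy	ribosomal protein S7
COG0052	COG0052	single_copy	ribosomal protein S2
COG0080	COG0080	single_copy	ribosomal protein L11
COG0081	COG0081	single_copy	ribosomal protein L1
COG0085	COG0085	single_copy	DNA-directed RNA polymerase beta subunit
COG0087	COG0087	single_copy	ribosomal protein L3
COG0088	COG0088	single_copy	ribosomal protein L4
COG0090	COG0090	single_copy	ribosomal protein L2
COG0091	COG0091	single_copy	ribosomal protein L22
COG0092	COG0092	single_copy	ribosomal protein S3
COG0093	COG0093	single_copy	ribosomal protein L14
COG0094	COG0094	single_copy	ribosomal protein L5
COG0096	COG0096	single_copy	ribosomal protein S8
COG0097	COG0097	single_copy	ribosomal protein L6P
COG0098	COG0098	single_copy	ribosomal protein S5
COG0099	COG0099	single_copy	ribosomal protein S13
COG0100	COG0100	single_copy	ribosomal protein S11
COG0102	COG0102	single_copy	ribosomal protein L13
COG0103	COG0103	single_copy	ribosomal protein S9
COG0124	COG0124	single_copy	histidyl-tRNA synthetase
COG0172	COG0172	single_copy	seryl-tRNA synthetase
COG0184	COG0184	single_copy	ribosomal protein S15P
COG0185	COG0185	single_copy	ribosomal protein S19
COG0186	COG0186	single_copy	ribosomal protein S17
COG0197	COG0197	single_copy	ribosomal protein L16
COG0200	COG0200	single_copy	ribosomal protein L15
COG0201	COG0201	single_copy	preprotein translocase SecY subunit
COG0202	COG0202	single_copy	DNA-directed RNA polymerase alpha subunit
COG0215	COG0215	single_copy	cysteinyl-tRNA synthetase
COG0256	COG0256	single_copy	ribosomal protein L18
COG0495	COG0495	single_copy	leucyl-tRNA synthetase
COG0522	COG0522	single_copy	ribosomal protein S4
COG0525	COG0525	single_copy	valyl-tRNA synthetase
COG0533	COG0533	single_copy	tRNA A37 threonylcarbamoyladenosine synthetase
COG0541	COG0541	single_copy	signal recognition particle GTPase
COG0552	COG0552	single_copy	signal recognition particle receptor
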