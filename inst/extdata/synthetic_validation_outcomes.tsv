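bait_id	prey_id	method	outcome
BAIT01	PREY01	coip_flag	validated
BAIT01	PREY01	bret	validated
BAIT02	PREY02	coip_flag	validated
BAIT02	PREY02	bret	validated
BAIT03	PREY03	coip_flag	validated
BAIT04	PREY04	coip_native	validated
BAIT05	PREY05	coip_flag	validated
BAIT06	PREY06	coip_native	validated
BAIT07	PREY07	coip_flag	validated
BAIT08	PREY08	coip_native	validated
BAIT09	PREY09	coip_flag	validated
BAIT10	PREY10	coip_native	validated
BAIT01	PREY11	coip_flag	validated
BAIT02	PREY12	coip_native	validated
BAIT03	PREY13	coip_flag	validated
BAIT04	PREY14	coip_native	validated
BAIT05	PREY15	coip_flag	validated
BAIT06	PREY16	coip_native	validated
BAIT07	PREY17	coip_flag	validated
BAIT08	PREY18	coip_native	validated
BAIT09	PREY19	coip_flag	validated
BAIT10	PREY20	coip_native	validated
BAIT01	PREY21	coip_flag	validated
BAIT02	PREY22	coip_native	validated
BAIT03	PREY23	coip_flag	not_validated
BAIT04	PREY24	coip_native	not_validated
BAIT05	PREY25	coip_flag	not_validated
BAIT06	PREY26	coip_native	not_validated
BAIT07	PREY27	coip_flag	not_validated
BAIT08	PREY28	coip_native	not_validated
BAIT09	PREY29	coip_flag	not_validated
BAIT10	PREY30	coip_native	not_validated
BAIT01	PREY31	coip_flag	not_validated
BAIT02	PREY32	coip_native	not_validated
BAIT03	PREY33	coip_flag	not_validated
BAIT04	PREY34	coip_native	not_validated
BAIT05	PREY35	bret	validated
BAIT06	PREY36	bret	validated
BAIT07	PREY37	bret	validated
BAIT08	PREY38	bret	validated
BAIT09	PREY39	bret	validated
BAIT10	PREY40	bret	validated
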