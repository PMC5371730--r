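bait_id	prey_id	method	outcome
KBAIT01	KPREY01	myth_retest	validated
KBAIT02	KPREY02	myth_retest	validated
KBAIT03	KPREY03	myth_retest	validated
KBAIT04	KPREY04	myth_retest	validated
KBAIT05	KPREY05	myth_retest	validated
KBAIT06	KPREY06	myth_retest	validated
KBAIT07	KPREY07	myth_retest	validated
KBAIT08	KPREY08	myth_retest	validated
KBAIT09	KPREY09	myth_retest	validated
KBAIT10	KPREY10	myth_retest	validated
KBAIT11	KPREY11	myth_retest	validated
KBAIT12	KPREY12	myth_retest	validated
KBAIT01	KPREY13	myth_retest	not_validated
KBAIT02	KPREY14	myth_retest	not_validated
KBAIT03	KPREY15	myth_retest	not_validated
KBAIT04	KPREY16	myth_retest	not_validated
KBAIT05	KPREY17	myth_retest	not_validated
KBAIT06	KPREY18	myth_retest	not_validated
KBAIT07	KPREY19	myth_retest	not_validated
KBAIT08	KPREY20	myth_retest	not_validated
KBAIT09	KPREY21	myth_retest	not_validated
KBAIT10	KPREY22	myth_retest	not_validated
KBAIT11	KPREY23	myth_retest	not_validated
KBAIT12	KPREY24	myth_retest	not_validated
KBAIT01	KPREY25	myth_retest	not_validated
KBAIT02	KPREY26	myth_retest	not_validated
KBAIT03	KPREY27	myth_retest	not_validated
KBAIT04	KPREY28	myth_retest	not_validated
KBAIT05	KPREY29	myth_retest	not_validated
KBAIT06	KPREY30	myth_retest	not_validated
KBAIT07	KPREY31	myth_retest	not_validated
KBAIT08	KPREY32	myth_retest	not_validated
KBAIT09	KPREY33	myth_retest	not_validated
KBAIT10	KPREY34	myth_retest	not_validated
KBAIT11	KPREY35	myth_retest	not_validated
KBAIT12	KPREY36	myth_retest	not_validated
KBAIT01	KPREY37	myth_retest	not_validated
KBAIT02	KPREY38	myth_retest	not_validated
KBAIT03	KPREY39	myth_retest	not_validated
KBAIT04	KPREY40	myth_retest	not_validated
KBAIT05	KPREY41	myth_retest	not_validated
KBAIT06	KPREY42	myth_retest	not_validated
KBAIT07	KPREY43	myth_retest	not_validated
KBAIT08	KPREY44	myth_retest	not_validated
KBAIT09	KPREY45	myth_retest	not_validated
KBAIT10	KPREY46	myth_retest	not_validated
KBAIT11	KPREY47	myth_retest	not_validated
KBAIT12	KPREY48	myth_retest	not_validated
KBAIT01	KPREY49	myth_retest	not_validated
KBAIT02	KPREY50	myth_retest	not_validated
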