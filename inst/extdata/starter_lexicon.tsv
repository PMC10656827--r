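term	variants	subtype	specificity	source	mean_rating	prop_at_least_2
child abuse		ABUSE	standard	investigator
abuse		ABUSE	standard	investigator
physical abuse		ABUSE	standard	investigator
violence		ABUSE	standard	investigator
neglect		ABUSE	standard	investigator
adverse childhood event	ACE	ABUSE	standard	investigator
childhood trauma		ABUSE	standard	investigator
alleged		ABUSE	standard	investigator
hit		ABUSE	standard	investigator
kick		ABUSE	standard	investigator
punch		ABUSE	standard	investigator
shove		ABUSE	standard	investigator
rape		SEXUAL_ABUSE	standard	investigator
date rape		SEXUAL_ABUSE	standard	investigator
sexual abuse	SA	SEXUAL_ABUSE	standard	investigator
sexual assault		SEXUAL_ABUSE	standard	investigator
molestation		SEXUAL_ABUSE	standard	investigator
pornography		SEXUAL_ABUSE	standard	investigator
inappropriate sexual behavior		SEXUAL_ABUSE	standard	investigator
injury to genital region		SEXUAL_ABUSE	standard	investigator
sexually transmitted disease		SEXUAL_ABUSE	standard	investigator
bruise		PHYSICAL_INDICATION	standard	investigator
genital bleeding		PHYSICAL_INDICATION	standard	investigator
vaginal bleeding		PHYSICAL_INDICATION	standard	investigator
burn		PHYSICAL_INDICATION	standard	investigator
malnutrition		PHYSICAL_INDICATION	standard	investigator
poor living conditions		PHYSICAL_INDICATION	standard	investigator
threaten		EMOTIONAL_INDICATION	standard	investigator
humiliate		EMOTIONAL_INDICATION	standard	investigator
ptsd		EMOTIONAL_INDICATION	standard	investigator
fear		EMOTIONAL_INDICATION	standard	investigator
coercion		EMOTIONAL_INDICATION	standard	investigator
child protective services	CPS	SERVICE	standard	investigator
foster care		SERVICE	standard	investigator
foster care support clinic	FCSC	SERVICE	standard	expert_round1
foster parents		SERVICE	standard	expert_round1
child advocacy center		SERVICE	standard	investigator
child abuse pediatrics		SERVICE	standard	expert_round1
police		SERVICE	low	investigator
law enforcement		SERVICE	low	expert_round1
case manager		SERVICE	low	expert_round1
case worker		SERVICE	low	expert_round1
incarcerated		SERVICE	low	expert_round1
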