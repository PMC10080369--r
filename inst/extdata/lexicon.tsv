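surface	category	tags
shot	shooting_verb	-
shooting	shooting_verb	-
fired	shooting_verb	-
discharged	shooting_verb	-
gun	weapon_term	-
handgun	weapon_term	-
rifle	weapon_term	-
pistol	weapon_term	-
firearm	weapon_term	-
gsw	injury_term	-
gunshot wound	injury_term	-
club	incident_location	location=outside
street	incident_location	location=outside
park	incident_location	location=outside
home	incident_location	location=inside
apartment	incident_location	location=inside
bar	incident_location	location=inside
police	police_actor	-
officer	police_actor	-
law enforcement	police_actor	-
cop	police_actor	-
accidentally	explicit_intent_accident	-
accidental discharge	explicit_intent_accident	-
unintentional	explicit_intent_accident	-
altercation	explicit_intent_assault	-
assault	explicit_intent_assault	-
assailant	explicit_intent_assault	-
suicide attempt	explicit_intent_self_harm	-
suicidal ideation	explicit_intent_self_harm	-
self inflicted	explicit_intent_self_harm	-
officer involved shooting	explicit_intent_legal	-
police involved shooting	explicit_intent_legal	-
legal intervention	explicit_intent_legal	-
circumstances remain unknown	no_info_attestation	-
unknown circumstances	no_info_attestation	-
intent unclear	no_info_attestation	-
police report	confusion_term	-
police department	confusion_term	-
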