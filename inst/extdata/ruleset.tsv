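id	kind	intent	clauses
explicit_accident	explicit_intent	accident	require_category=explicit_intent_accident;forbid_modifier=negated,historical
explicit_assault	explicit_intent	assault	require_category=explicit_intent_assault;forbid_modifier=negated,historical
explicit_self_harm	explicit_intent	self_harm	require_category=explicit_intent_self_harm;forbid_modifier=negated,historical
explicit_legal	explicit_intent	legal_intervention	require_category=explicit_intent_legal;forbid_modifier=negated,historical
no_info_attested	explicit_intent	unknown	require_category=no_info_attestation;forbid_modifier=negated,historical
self_directed_shooting	role	self_harm	event_role=self_directed
assault_shooter	role	assault	event_role=other_shooter
legal_shooter	role	legal_intervention	event_role=police_shooter
location_inside	location	-	require_tag=incident_location:location=inside;forbid_modifier=negated,historical
location_outside	location	-	require_tag=incident_location:location=outside;forbid_modifier=negated,historical
high_info_note	info_density	-	pair_count_cmp=per_note_max ge high
low_info_case	info_density	-	pair_count_cmp=per_case lt low
no_explicit_intent	meta	-	count_explicit=eq 0
conflicting_intent	meta	-	distinct_intents=ge 2
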