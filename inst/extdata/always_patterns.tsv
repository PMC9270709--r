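pattern	label	author	created_round
(remains|is|appears) (confused|agitated|disoriented)	POSITIVE	synthetic-expert	0
altered mental status with	POSITIVE	synthetic-expert	0
waxing and waning mental status	POSITIVE	synthetic-expert	1
restraints (applied|in place) for agitation	POSITIVE	synthetic-expert	1
acute encephalopathy likely	POSITIVE	synthetic-expert	2
became agitated	POSITIVE	synthetic-expert	2
no (evidence|signs) of delirium	NEGATIVE	synthetic-expert	0
alert and oriented x3	NEGATIVE	synthetic-expert	0
denies hallucination	NEGATIVE	synthetic-expert	1
no acute encephalopathy	NEGATIVE	synthetic-expert	2
confused about (medication|discharge)	NEITHER	synthetic-expert	0
restraints policy paperwork	NEITHER	synthetic-expert	1
delirium screening education	NEITHER	synthetic-expert	2
history of psychosis in	NEITHER	synthetic-expert	2
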