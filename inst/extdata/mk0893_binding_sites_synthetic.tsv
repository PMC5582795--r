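position	residue	label
329	L	MK-0893
345	F	MK-0893
346	R	MK-0893
349	K	MK-0893
350	S	MK-0893
352	L	MK-0893
353	T	MK-0893
399	L	MK-0893
404	N	MK-0893
405	K	MK-0893
341	A	MK-0893-synthetic
398	V	MK-0893-synthetic
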