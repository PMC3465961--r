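egl-4	egl-30
egl-4	goa-1
egl-4	tax-2
goa-1	dgk-1
gpa-3	gpa-13
gpa-3	odr-3
gpa-5	arr-1
odr-1	tax-4
odr-3	arr-1
odr-3	daf-11
odr-3	egl-4
odr-3	odr-1
odr-3	rgs-3
tax-2	eat-4
tax-6	tax-2
tax-6	tax-4
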