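gene	category
gpa-3	regulator_class_1
odr-3	regulator_class_1
gpa-5	regulator_class_1
gpa-13	regulator_class_1
arr-1	regulator_class_1
rgs-3	regulator_class_1
egl-4	regulator_class_2
tax-6	regulator_class_2
odr-1	regulator_class_2
daf-11	regulator_class_2
tax-2	regulator_class_2
tax-4	regulator_class_2
goa-1	actuator
egl-30	actuator
dgk-1	actuator
eat-4	actuator
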