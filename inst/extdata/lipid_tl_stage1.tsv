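exposure	coefficient	B	S	t	P	R2
APOA1	Intercept	2.37e-4	3.08e-4	0.77	4.43e-1	2.55e-4
APOA1	Predicted	-1.76e-3	7.82e-3	-0.23	8.23e-1	NA
APOB	Intercept	-2.59e-4	4.03e-4	-0.64	5.22e-1	1.19e-1
APOB	Predicted	2.97e-2	7.44e-3	3.99	1.17e-4	NA
HDL	Intercept	2.17e-4	2.97e-4	0.73	4.64e-1	4.61e-4
HDL	Predicted	2.35e-3	7.12e-3	0.33	7.42e-1	NA
LDL	Intercept	2.36e-4	4.00e-4	0.59	5.57e-1	1.10e-1
LDL	Predicted	3.32e-2	9.53e-3	3.48	7.44e-4	NA
TG	Intercept	1.22e-4	3.07e-4	0.39	6.91e-1	6.05e-2
TG	Predicted	2.17e-2	6.67e-3	3.25	1.40e-3	NA
TC	Intercept	1.24e-4	3.60e-4	0.35	7.31e-1	8.76e-2
TC	Predicted	3.45e-2	1.13e-2	3.05	2.93e-3	NA
RC	Intercept	1.86e-4	7.56e-4	0.25	8.09e-1	6.93e-1
RC	Predicted	8.37e-2	1.31e-2	6.37	5.35e-6	NA
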