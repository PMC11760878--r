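exposure	outcome	Bm	Sm	Z	Pm
TG	LUNG	7.46e-3	2.62e-3	2.85	4.34e-3
TG	HTC	1.21e-4	4.66e-5	2.60	9.28e-3
TG	ESCA	5.51e-3	3.22e-3	1.71	8.66e-2
TC	LUNG	1.19e-2	4.37e-3	2.71	6.64e-3
TC	HTC	1.93e-4	7.73e-5	2.50	1.26e-2
TC	ESCA	8.76e-3	5.21e-3	1.68	9.25e-2
RC	LUNG	2.88e-2	6.62e-3	4.35	1.38e-5
RC	HTC	4.68e-4	1.30e-4	3.59	3.35e-4
RC	ESCA	2.13e-2	1.11e-2	1.92	5.45e-2
LDL	LUNG	1.14e-2	3.80e-3	3.00	2.67e-3
LDL	HTC	1.86e-4	6.84e-5	2.72	6.63e-3
LDL	ESCA	8.43e-3	4.83e-3	1.74	8.10e-2
APOB	LUNG	1.02e-2	3.09e-3	3.31	9.27e-4
APOB	HTC	1.66e-4	5.65e-5	2.94	3.32e-3
APOB	ESCA	7.54e-3	4.19e-3	1.80	7.19e-2
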