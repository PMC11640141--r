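id	source	database	form	intercept	terms	quad	a	b	c	predictor	reported_rmse	reported_r2	sign_anomaly
mills_linear	extant	external	linear	5.9299999999999997	DMI=0.92000000000000004		NA	NA	NA	NA	NA	NA	FALSE
mills_mono	extant	external	monomolecular	NA			56.270000000000003	0	0.028000000000000001	DMI	NA	NA	FALSE
ipcc2006	extant	external	linear	0	GEI=0.065000000000000002		NA	NA	NA	NA	NA	NA	FALSE
ellis2007	extant	external	linear	3.2719999999999998	DMI=0.73599999999999999		NA	NA	NA	NA	NA	NA	FALSE
yan2009	extant	external	linear	0.58199999999999996	DMI=1.3999999999999999		NA	NA	NA	NA	NA	NA	FALSE
ramin_huhtanen2013	extant	external	quadratic	0.79700000000000004	DMI=1.427	DMI=-0.02	NA	NA	NA	NA	NA	NA	FALSE
patra	extant	external	monomolecular	NA			35.210000000000001	0.25	0.035400000000000001	DMI	NA	NA	FALSE
eq1b	developed	beef	linear	0.91879999999999995	DMI=0.8196		NA	NA	NA	NA	2.1299999999999999	0.82999999999999996	FALSE
eq2b	developed	beef	linear	2.4904000000000002	MEI=0.065699999999999995		NA	NA	NA	NA	2.2400000000000002	0.76000000000000001	FALSE
eq3b	developed	beef	linear	2.5491999999999999	NDFI=1.8401000000000001		NA	NA	NA	NA	1.96	0.72999999999999998	FALSE
eq4b	developed	beef	linear	0.94620000000000004	DMI=0.43680000000000002;NDFI=1.1567000000000001		NA	NA	NA	NA	1.5700000000000001	0.82999999999999996	FALSE
eq5b	developed	beef	linear	0.019	DMI=0.80579999999999996;ADFI=0.64900000000000002		NA	NA	NA	NA	2.1099999999999999	0.69999999999999996	FALSE
eq6b	developed	beef	linear	-0.88480000000000003	MEI=0.066900000000000001;ADFI=2.1255000000000002		NA	NA	NA	NA	1.98	0.72999999999999998	FALSE
eq7b	developed	beef	linear	1.6836	MEI=0.034200000000000001;NDFI=1.2202		NA	NA	NA	NA	1.5700000000000001	0.82999999999999996	FALSE
eq8b	developed	beef	linear	1.6063000000000001	DMI=0.42559999999999998;NDFI=1.2213000000000001;ADFI=-0.47499999999999998		NA	NA	NA	NA	1.55	0.82999999999999996	FALSE
beef_exp1	developed	beef	exponential	NA			NA	-1.264	0.30940000000000001	DMI	1.21	0.72999999999999998	TRUE
beef_exp2	developed	beef	exponential	NA			NA	-3.0019999999999998	0.0172	MEI	2.3300000000000001	0.69999999999999996	TRUE
beef_power	developed	beef	power	NA			NA	1.0389999999999999	0.94740000000000002	DMI	2.2799999999999998	0.67000000000000004	FALSE
eq1d	developed	dairy	linear	-6.9931000000000001	BW=0.0448		NA	NA	NA	NA	4.5800000000000001	0.55000000000000004	FALSE
eq2d	developed	dairy	linear	0.75670000000000004	DMI=1.0916999999999999		NA	NA	NA	NA	2.73	0.83999999999999997	FALSE
eq3d	developed	dairy	linear	5.5616000000000003	MEI=0.078899999999999998		NA	NA	NA	NA	4.4299999999999997	0.79000000000000004	FALSE
eq4d	developed	dairy	linear	1.6798999999999999	NDFI=2.7698		NA	NA	NA	NA	3.4500000000000002	0.73999999999999999	FALSE
eq5d	developed	dairy	linear	0.39889999999999998	DMI=0.86850000000000005;NDFI=0.66749999999999998		NA	NA	NA	NA	2.6600000000000001	0.84999999999999998	FALSE
eq6d	developed	dairy	linear	0.86419999999999997	DMI=1.1024;ADFI=-0.1051		NA	NA	NA	NA	2.73	0.83999999999999997	FALSE
eq7d	developed	dairy	linear	2.9962	MEI=0.064600000000000005;ADFI=1.8279000000000001		NA	NA	NA	NA	4.2400000000000002	0.62	FALSE
eq8d	developed	dairy	linear	1.7104999999999999	MEI=0.0083999999999999995;NDFI=2.5447000000000002		NA	NA	NA	NA	3.4300000000000002	0.75	FALSE
eq9d	developed	dairy	linear	0.52459999999999996	DMI=0.88049999999999995;NDFI=0.66910000000000003;ADFI=-0.1237		NA	NA	NA	NA	2.6499999999999999	0.88	FALSE
eq10d	developed	dairy	linear	-3.0617000000000001	MEI=0.0147;NDFI=2.4028;roughage=0.0070000000000000001		NA	NA	NA	NA	3.1800000000000002	0.78000000000000003	FALSE
dairy_gompertz	developed	dairy	gompertz	NA			39.310000000000002	1.3959999999999999	0.1002	DMI	3.3399999999999999	0.80000000000000004	FALSE
dairy_exp1	developed	dairy	exponential	NA			NA	-4.0759999999999996	0.076499999999999999	DMI	1.27	0.85999999999999999	TRUE
dairy_exp2	developed	dairy	exponential	NA			NA	-4.8399999999999999	0.0054999999999999997	MEI	1.5	0.68999999999999995	TRUE
dairy_power	developed	dairy	power	NA			NA	0.88700000000000001	1.085	DMI	2.6200000000000001	0.88	FALSE
eq1c	developed	combined	linear	0.052900000000000003	DMI=1.0468999999999999		NA	NA	NA	NA	3.04	0.82999999999999996	FALSE
eq2c	developed	combined	linear	3.8799999999999999	MEI=0.070999999999999994		NA	NA	NA	NA	1.3600000000000001	0.81000000000000005	FALSE
eq3c	developed	combined	linear	0.94540000000000002	NDFI=2.6638000000000002		NA	NA	NA	NA	1.4299999999999999	0.78000000000000003	FALSE
eq4c	developed	combined	linear	-0.3821	DMI=0.59319999999999995;NDFI=1.3849		NA	NA	NA	NA	0.54000000000000004	0.84999999999999998	FALSE
eq5c	developed	combined	linear	-0.60419999999999996	DMI=1.0087999999999999;ADFI=0.54220000000000002		NA	NA	NA	NA	1.45	0.79000000000000004	FALSE
eq6c	developed	combined	linear	-0.29239999999999999	MEI=0.070199999999999999;ADFI=2.3214999999999999		NA	NA	NA	NA	1.52	0.60999999999999999	FALSE
eq7c	developed	combined	linear	0.70850000000000002	MEI=0.0167;NDFI=2.3096000000000001		NA	NA	NA	NA	1.5600000000000001	0.79000000000000004	FALSE
eq8c	developed	combined	linear	-0.34960000000000002	DMI=0.59409999999999996;NDFI=1.3879999999999999;ADFI=-0.0276		NA	NA	NA	NA	1.47	0.84999999999999998	FALSE
combined_gompertz	developed	combined	gompertz	NA			36.229999999999997	0.95599999999999996	0.10580000000000001	DMI	3.3399999999999999	0.73999999999999999	FALSE
combined_exp	developed	combined	exponential	NA			NA	-3.6669999999999998	0.085500000000000007	DMI	1.6200000000000001	0.81000000000000005	TRUE
combined_power1	developed	combined	power	NA			NA	0.78200000000000003	1.1087	DMI	2.6299999999999999	0.83999999999999997	FALSE
combined_power2	developed	combined	power	NA			NA	0.20499999999999999	0.8528	MEI	3.5800000000000001	0.69999999999999996	FALSE
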