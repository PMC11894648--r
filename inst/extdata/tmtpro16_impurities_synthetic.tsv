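# SYNTHETIC impurity correction template for TMTpro 16-plex.
# Magnitudes are plausible stand-ins for a vendor certificate of
# analysis, NOT measured values: ~6-7% +1 same-type (13C) leakage,
# ~0.6-1.3% -1 same-type leakage, and the C->N cross leakage of the
# 126 reporter into 127N.
source	destination	percent
126	127C	7.2
126	127N	0.7
127N	128N	6.8
127C	128C	6.5
127C	126	1.1
128N	129N	6.2
128N	127N	0.9
128C	129C	7.0
128C	127C	1.2
129N	130N	6.6
129N	128N	0.8
129C	130C	6.1
129C	128C	1.0
130N	131N	5.9
130N	129N	1.1
130C	131C	6.4
130C	129C	0.7
131N	132N	6.9
131N	130N	0.9
131C	132C	5.8
131C	130C	1.3
132N	133N	6.0
132N	131N	0.8
132C	133C	6.3
132C	131C	1.0
133N	134N	5.7
133N	132N	1.2
133C	132C	0.6
134N	133N	0.9
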