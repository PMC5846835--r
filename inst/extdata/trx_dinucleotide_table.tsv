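# TRX dinucleotide flexibility scale: percent BII occupancy of the
# phosphate linkage in each dinucleotide step, read 5'->3'.
# 0 = stiff (always BI), 43 = very flexible (nearly half time in BII).
# Transcribed from the published NMR-derived scale; values are symmetric
# under reverse complement because each base-pair step carries one value.
AA	13
AC	4
AG	8
AT	0
CA	42
CC	22
CG	43
CT	8
GA	23
GC	34
GG	22
GT	4
TA	30
TC	23
TG	42
TT	13
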