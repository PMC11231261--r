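protein_id	unique_peptides	psm	intensity_mvb	intensity_lysate
SYN0001	1	1	3496	10646
SYN0002	2	6	500768	1268675
SYN0003	2	6	4918	16395
SYN0004	1	5	180202	385455
SYN0005	1	3	91120	113322
SYN0006	1	2	197098	106498
SYN0007	2	6	146074	207899
SYN0008	1	4	19233	16828
SYN0009	36	109	106288	218847
SYN0010	13	40	15934	19701
SYN0011	25	77	344071	368471
SYN0012	6	18	2027894	649893
SYN0013	30	91	256692	241122
SYN0014	32	97	655091	414622
SYN0015	13	39	12955	13073
SYN0016	31	95	78094	273797
SYN0017	31	93	770506	94581
SYN0018	13	41	18281	22601
SYN0019	7	23	52609	14148
SYN0020	4	13	37040	61881
SYN0021	29	87	6108	16203
SYN0022	35	106	1969787	1152502
SYN0023	5	16	12647	16537
SYN0024	30	91	20061811	1280393
SYN0025	26	80	32867	27940
SYN0026	15	47	233363	168918
SYN0027	34	103	47975	30378
SYN0028	13	41	40858	34237
SYN0029	36	110	1013216	2387870
SYN0030	37	113	119636	163833
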