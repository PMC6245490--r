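name	pattern
1-10	[FILVW]xxxxxxxx[FILVW]
1-5-10	[FILVW]xxx[FAILVW]xxxx[FILVW]
Basic 1-5-10	[RK][RK][RK][FAILVW]xxx[FILVW]xxxx[FILVW]
1-12	[FILVW]xxxxxxxxxx[FILVW]
1-14	[FILVW]xxxxxxxxxxxx[FILVW]
1-8-14	[FILVW]xxxxxx[FAILVW]xxxxx[FILVW]
1-5-8-14	[FILVW]xxx[FAILVW]xx[FAILVW]xxxxx[FILVW]
Basic 1-8-14	[RK][RK][RK][FILVW]xxxxxx[FAILVW]xxxxx[FILVW]
1-16	[FILVW]xxxxxxxxxxxxxx[FILVW]
IQ	[FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]
IQ-like	[FILV]Qxxx[RK]xxxxxxxx
IQ-2A	[IVL]QxxxRxxxx[VL][KR]xW
IQ-2B	[IL]QxxCxxxxKxRxW
IQ unconventional	[IVL]QxxxRxxxx[RK]xx[FILVWY]
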