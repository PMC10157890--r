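sequence,mean,sd
QLSK(ac)WP,0.020,0.006
RMFK(ac)QFN,0.015,0.014
SLK(ac)FG,0.0086,0.0017
GRAK(ac)YWL,0.007,0.003
ISK(ac)FD,0.0049,0.0014
AFK(ac)WR,0.0040,0.0009
PLWK(ac)GIG,0.0035,0.0021
FAK(ac)WR,0.0032,0.0015
RIPK(ac)EQW,0.0031,0.0015
RFTK(ac)CLR,0.0030,0.0016
AFGK(ac)YCR,0.0029,0.0004
PVK(ac)FI,0.0025,0.0005
YSK(ac)GF,0.0020,0.0010
YQK(ac)WD,0.0018,0.0006
FSK(ac)AF,0.0016,0.0006
TGNK(ac)YVP,0.0011,0.0006
TGK(ac)TF,0.0011,0.0002
VIK(ac)GF,0.0009,0.0001
LGGK(ac)QRA,0.0006,0.0004
LHK(ac)LL,0.0004,0.0003
LSGK(ac)EIN,,
EIGK(ac)TLA,,
EVGK(ac)LLN,,
SDK(ac)TI,,
VGGK(ac)DFE,,
GVGK(ac)YIN,,
SDMK(ac)HWP,,
GTAK(ac)SVT,,
SHLK(ac)AHL,,
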