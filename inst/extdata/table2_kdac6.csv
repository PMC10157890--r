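sequence,mean,sd
AFGK(ac)YCR,0.20,0.09
AFK(ac)WR,0.15,0.06
QLSK(ac)WP,0.14,0.03
TGNK(ac)YVP,0.10,0.04
GRAK(ac)YWL,0.100,0.009
GAGK(ac)HVP,0.06,0.03
GVGK(ac)YIN,0.055,0.024
LSGK(ac)GNP,0.042,0.009
TDGK(ac)VFQ,0.026,0.024
SHLK(ac)AHL,0.024,0.013
LSGK(ac)EIN,0.024,0.005
QATK(ac)DAG,0.022,0.006
SDK(ac)TI,0.020,0.013
SLK(ac)FG,0.020,0.009
PVK(ac)FI,0.017,0.005
ISK(ac)FD,0.013,0.007
SDMK(ac)HWP,0.013,0.009
IIDK(ac)SQL,0.011,0.009
YFSK(ac)HN,0.010,0.006
LDHK(ac)FDL,0.009,0.007
GTAK(ac)SVT,,
TLSK(ac)LHE,,
PSPK(ac)VSD,,
PEAK(ac)SLL,,
FFHK(ac)VNE,,
VLEK(ac)LGE,,
LISK(ac)IRE,,
DLAK(ac)VQR,,
PDRK(ac)PFP,,
SVRK(ac)GIM,,
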