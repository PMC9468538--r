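# Ten published durum wheat quality GWAS compiled for hotspot meta-analysis.
# traits: comma-separated trait codes reported by each study.
study_id	panel	size	n_mta	traits
s01	Agrogen	104	19	AX
s02	Agrogen	230	7	BG
s03	Durum collection (7 subspecies)	124	6	YPC
s04	Worldwide elite durum wheat	93	20	YPC
s05	Mediterranean landraces	172	14	GPC,GS,TW,YPC
s06	Cultivars and inbred lines (1997-2014)	243	163	CLOSS,Color,CWT,dif,FIRM,GLUT,GPC,GS,MIXO,PPO,SASH,SEXT,SPROT,SV,TEXT,VIT,WG,WTS,YPC
s07	Italian durum breeding lines	79	44	Gli,Gli+Glu,HMW/LMW,IP,TPT
s08	Ethiopian durum wheat	192	20	a*,b*,L*,GL,GW
s09	Canadian durum breeding lines	192	80	DEE,DOE,DOTE,GPC,GS,PLOSS,PRLOSS,YPC
s10	Canadian durum wheat collection	169	22	PLOSS,YPC
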