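ESG	estrogen signaling (representative members)	Esr1	Esr2	Gper1	Shc1	Sos1	Grb2	Hras	Kras	Raf1	Map2k1	Mapk1	Mapk3	Pik3ca	Pik3cb	Akt1	Akt2	Plcb1	Plcb2	Itpr1	Itpr2	Prkaca	Prkacb	Adcy1	Adcy2	Adcy5	Adcy6	Adcy9	Gnai1	Gnai2	Gnaq	Gnas	Gng2	Gng3	Kcnj3	Kcnj6	Creb1	Sp1	Jun	Fos	Hspa8	Hsp90aa1	Ctsd	Pgr	Mmp2	Mmp9	Nos3	Oxt	Calm1	Calm2	Cyp2j3	Src	Arrb2	Gsk3a
GLU	glutamatergic synapse (representative members)	Gria1	Gria2	Gria3	Gria4	Grin1	Grin2a	Grin2b	Grik1	Grik2	Grik5	Grm1	Grm2	Grm3	Grm5	Grm7	Slc17a6	Slc17a7	Slc1a2	Slc1a3	Slc38a1	Dlg4	Shank1	Shank2	Homer1	Gng2	Gnai1	Gnaq	Adcy1	Plcb1	Prkca	Ppp3ca	Cacna1a	Glul	Gls
GABA	GABAergic synapse (representative members)	Gabra1	Gabra2	Gabra4	Gabra5	Gabrb1	Gabrb2	Gabrb3	Gabrg1	Gabrg2	Gabbr1	Gabbr2	Gad1	Gad2	Slc6a1	Slc6a11	Slc32a1	Abat	Gphn	Adcy2	Gnai1	Gnai2	Gng2	Prkacb	Src	Cacna1b	Plcl1	Trak2	Nsf
ACH	cholinergic synapse (representative members)	Chrna3	Chrna4	Chrna7	Chrnb2	Chrm1	Chrm2	Chrm3	Chrm4	Chrm5	Chat	Ache	Slc5a7	Slc18a3	Kcnq2	Kcnq3	Camk2a	Pik3ca	Akt1	Jak2	Fyn	Adcy1	Gnaq	Gnai1	Gng2	Plcb1	Creb1	Fos	Itpr1
DA	dopaminergic synapse (representative members)	Drd1	Drd2	Drd3	Drd4	Drd5	Th	Ddc	Slc6a3	Slc18a2	Comt	Maoa	Maob	Gsk3a	Gsk3b	Akt1	Ppp2ca	Arrb2	Camk2a	Prkaca	Gng2	Gnai1	Gnaq	Gnas	Plcb1	Itpr1	Creb1	Fos	Calm1	Scn1a	Kif5a
5HT	serotonergic synapse (representative members)	Htr1a	Htr1b	Htr2a	Htr2c	Htr3a	Htr4	Htr5a	Htr6	Htr7	Tph1	Tph2	Ddc	Slc6a4	Slc18a2	Maoa	Gnai1	Gnaq	Gnas	Gng2	Plcb1	Prkca	Adcy5	Braf	Raf1	Map2k1	Mapk1	Mapk3	App	Casp3	Cyp2j3	Alox5	Itpr1
APO	apoptosis (representative members)	Casp3	Casp6	Casp7	Casp8	Casp9	Bax	Bak1	Bcl2	Bcl2l1	Bid	Bad	Apaf1	Cycs	Tp53	Fas	Faslg	Tnf	Tnfrsf1a	Tradd	Fadd	Birc2	Birc3	Xiap	Parp1	Aifm1	Endog	Ctsd	Jun	Fos	Akt1	Pik3ca	Nfkb1	Map3k5	Mapk8	Atm
CC	cell cycle (representative members)	Ccnd1	Ccnd2	Ccne1	Ccna2	Ccnb1	Cdk1	Cdk2	Cdk4	Cdk6	Cdkn1a	Cdkn1b	Cdkn2a	Rb1	E2f1	E2f2	Tp53	Mdm2	Wee1	Chek1	Chek2	Atm	Atr	Cdc16	Cdc20	Cdc25a	Cdc25b	Anapc1	Bub1	Bub1b	Mad2l1	Plk1	Smad3	Myc	Gsk3b	Abl1
SVC	synaptic vesicle cycle (representative members)	Syt1	Syt2	Stx1a	Stx1b	Stxbp1	Snap25	Vamp2	Rab3a	Rims1	Unc13b	Cplx1	Cplx2	Nsf	Napa	Dnm1	Dnm2	Clta	Cltb	Cltc	Ap2a1	Ap2b1	Slc17a7	Slc6a1	Slc6a3	Slc6a4	Slc18a2	Slc18a3	Slc32a1	Atp6v0c	Atp6v1a
LTP	long-term potentiation (representative members)	Grin1	Grin2a	Grin2b	Gria1	Gria2	Grm1	Grm5	Calm1	Calm2	Camk2a	Camk2b	Camk4	Ppp1ca	Ppp1cc	Ppp3ca	Ppp3r1	Prkaca	Prkacb	Prkca	Prkcb	Adcy1	Adcy8	Creb1	Ep300	Braf	Raf1	Map2k1	Map2k2	Mapk1	Mapk3	Rap1a	Itpr1	Plcb1	Gnaq
LTD	long-term depression (representative members)	Gria1	Gria2	Gria3	Grm1	Grid2	Cacna1a	Gnaq	Gnai1	Gnas	Plcb1	Plcb4	Prkca	Prkcb	Prkcg	Ppp2ca	Ppp2cb	Itpr1	Calm1	Gucy1a1	Gucy1b1	Prkg1	Braf	Raf1	Map2k1	Mapk1	Mapk3	Igf1	Igf1r	Lyn	Crh
ALZ	Alzheimer disease (representative members)	App	Apoe	Psen1	Psen2	Bace1	Aph1a	Ncstn	Mapt	Gsk3b	Cdk5	Capn1	Capn2	Casp3	Casp7	Casp8	Casp9	Cycs	Apaf1	Bid	Tnf	Il1b	Ide	Lpl	Lrp1	Sorl1	Snca	Grin1	Grin2a	Grin2b	Itpr1	Calm1	Atp2a2	Ryr3	Ndufs1	Sdha	Uqcrc1	Cox4i1	Atp5f1a	Mme
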