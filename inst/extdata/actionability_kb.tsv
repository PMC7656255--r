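gene_symbol	alteration_matcher	protein_change	tumor_context	level	drugs	oncogenic_classes
PIK3CA	any_oncogenic	NA	breast	L1	alpelisib	missense,inframe_indel
BRCA1	truncating	NA	breast	L1	olaparib,talazoparib	NA
BRCA2	truncating	NA	breast	L1	olaparib,talazoparib	NA
ERBB2	amplification	NA	breast	L1	trastuzumab,pertuzumab,ado-trastuzumab emtansine,lapatinib,neratinib	NA
AKT1	exact_protein_change	p.E17K	breast	L3A	capivasertib,ipatasertib	NA
PTEN	truncating	NA	breast	L3A	capivasertib	NA
ESR1	any_oncogenic	NA	breast	L3A	fulvestrant	missense
ERBB2	any_oncogenic	NA	breast	L3A	neratinib	missense,inframe_indel
TSC1	truncating	NA	other	L2B	everolimus	NA
TSC2	truncating	NA	other	L2B	everolimus	NA
CDKN2A	any_oncogenic	NA	other	L3B	palbociclib,ribociclib,abemaciclib	missense,nonsense,frameshift,splice_site
FGFR1	amplification	NA	other	L3B	erdafitinib	NA
KRAS	exact_protein_change	p.G12C	other	L3B	sotorasib	NA
MET	amplification	NA	other	L3B	crizotinib	NA
NF1	truncating	NA	other	L4	trametinib	NA
NOTCH1	truncating	NA	other	L4	investigational gamma-secretase inhibitors	NA
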