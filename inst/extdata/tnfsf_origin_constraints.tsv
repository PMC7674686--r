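# Origin constraints for the TNFSF orthology groups: the five-cluster model
# of early vertebrate TNF-superfamily evolution encoded as data.  Thirteen
# groups are 2R ohnologs (origin WGD2) descending from three pre-WGD
# progenitors: one on ancestral chromosome 9 (TNF, FASL and 4-1BBL clusters;
# the 4-1BBL pair descends from a tandem duplicate that arose between the
# two WGDs, hence its own quartet id) and two on ancestral chromosome 16
# (CD40L and EDA clusters).  BALM and TNFSF-Fish2 are tandem duplicates that
# arose on the vertebrate stem after WGD2; the remaining tandem groups arose
# later on the indicated branches.  TNFSF-Fish1 and TNFSF-New are left
# unconstrained (their deep placement is uncertain).
group	cluster	origin	parent_group	branch	after_event	progenitor	quartet	paralogon
TNFSF1/2	TNF	WGD2				P_chr9	Q_chr9_direct	9
TNFSF15	TNF	WGD2				P_chr9	Q_chr9_direct	9
TNFSF6	FASL	WGD2				P_chr9	Q_chr9_direct	9
TNFSF14	FASL	WGD2				P_chr9	Q_chr9_direct	9
TNFSF4	4-1BBL	WGD2				P_chr9	Q_chr9_tandem	9
TNFSF9	4-1BBL	WGD2				P_chr9	Q_chr9_tandem	9
TNFSF5	CD40L	WGD2				P_chr16_CD40		16
TNFSF10	CD40L	WGD2				P_chr16_CD40		16
TNFSF11	CD40L	WGD2				P_chr16_CD40		16
TNFSF12	CD40L	WGD2				P_chr16_CD40		16
EDA	EDA	WGD2				P_chr16_EDA		16
TNFSF13	EDA	WGD2				P_chr16_EDA		16
TNFSF13B	EDA	WGD2				P_chr16_EDA		16
BALM	EDA	tandem	EDA	vertebrate_ancestor	WGD2			16
TNFSF-Fish2	TNF	tandem	TNFSF15	vertebrate_ancestor	WGD2			9
TNFSF3	TNF	tandem	TNFSF1/2	sarcopterygian_ancestor				9
TNFSF8	TNF	tandem	TNFSF15	sarcopterygian_ancestor				9
TNFSF-Fish5	TNF	tandem	TNFSF15	gnathostome_ancestor				9
TNFSF-Fish3	CD40L	tandem	TNFSF5	gnathostome_ancestor				16
TNFSF-Fish4	CD40L	tandem	TNFSF5	gnathostome_ancestor				16
TNFSF7	4-1BBL	tandem	TNFSF9	Homo_sapiens				9
TNFSF18	4-1BBL	tandem	TNFSF4	Homo_sapiens				9
TNFSF-Fish1	TNF	unconstrained						unknown
TNFSF-New	unassigned	unconstrained						unknown
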