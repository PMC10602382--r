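category	gene	sequence
net_negative	SIS2	KNNEEEDDDEDEEEDDDEEEDTEDKNENNNDDDDDDDDDDDDDDDDDDDDDDDDEDEDEAE
net_negative	RNA1	DLLQSKFDDLEVDDFEEVDSEDEEGEDEEDEDEDEKLEEIETERLEKELLEVQVDDLAERLAETEIK
net_negative	COP1	EEPLGEENFNDEDIGEDEGAWDLGDEDLDVGEELPEEVEQGE
near_neutral	RIO1	EEFSDDEEDGSSGSEEDDEEEGEYYDDDEPKVLKGKKHEDKDLKKLRKQEAKDAKREKRKTKVKKHIKKKLVKKTKSKK
near_neutral	SEC3	EVNKRYELEQQQQQEEAELRRLEEQKRLQLQKENEMKRLEEERRIKQEERKRQMELEHQRQLEEEERKRQMELEAKKQMELKRQRQFEEEQRLKKERELLEIQRKQREQETAERLKKEEQEALAKKEEEEKSKRNKVDNE
near_neutral	MNN4	KLLEERKRREKKKKEEEEKKKKEEEEKKKKEEEEKKKKEEEEKKKKEEEEKKKKEEEEKKKQEEEEKKKKEEEEKKKQEEGEKMKNEDEENKKNEDEEKKKNEEEEKKKQEEKNKKNEDEEKKKQEEEEKKKNEEEEKKKQEE
net_positive	TMA23	KGKKRRRRDEDDNKVKRKKLKKDKKTSNDSESKKKKKKKSKKESKKGKKSKHSSDEGDKSKHKKSKKSKKHKKEESSARRDRKE
net_positive	ZDS2	KKNSLEKRLAKLFKRKQHNGTCKSDVKVIKKSVKKELKKK
net_positive	FAF1	KVKKGQFRKIESTYKKDIERRIGGSIKARDKEKATKRERGLK
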