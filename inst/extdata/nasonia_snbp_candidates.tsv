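gene	label	go_summary	rpkm_testis	pI
LOC100116183	Nv-PL1	C: nucleosome; F: DNA binding; P: nucleosome assembly	232063	10.7
LOC100118976	Nv-PL2	C: nucleosome; F: DNA binding; P: nucleosome assembly	44374	11.5
LOC100120046		C: nucleus, chromosome; F: DNA binding, phosphatase/methyltransferase activity, zinc ion binding; P: chromatin organization and others	18950	9.5
LOC100678761		C: nucleus; F: DNA binding, NAD+ ADP-ribosyltransferase activity, zinc ion binding; P: metabolic processes	14643	8.4
LOC100114216		C: nucleus; F: DNA-binding transcription factor activity, zinc ion binding; P: regulation of DNA-templated transcription	12063	8.1
LOC103316131		uncharacterized	5086	10.7
LOC103316943		C: nucleus; F: DNA binding	4967	10.7
LOC116417036		C: membrane; F: nucleic acid binding; P: DNA integration	2598	8.1
LOC116416958		P: DNA biosynthetic process	1197	8.2
LOC103316653		C: membrane, sarcoplasmic reticulum; F: calcium channel activity; P: transcription regulation, histone modification, calcium transport	1002	9.3
LOC100119399		C: nucleosome, extracellular region, nucleoplasm; F: DNA binding, structural constituent of chromatin; P: nucleosome assembly, telomere organization	635	11.5
LOC103316712		P: DNA biosynthetic process	598	8.8
LOC107980474		C: transcription factor TFIIH core complex, chromosome; P: nucleotide-excision repair, chromatin remodeling	149	9.2
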