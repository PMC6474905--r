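no	species	section	accession	len_its	len_58s	len_its1	len_its2	gc_its	gc_58s	gc_its1	gc_its2
1	Dendrobium longicorna	Formosae	MK522197	638	163	228	247	53.9	58.3	52.6	52.2
2	Dendrobium infundibulum	Formosae	MK522210	639	163	229	247	54.1	57.7	53.7	52.2
3	Dendrobium trigonopus	Formosae	MK522215	643	163	233	247	52.7	55.8	52.8	50.6
4	Dendrobium bellatulum	Formosae	MK522222	630	163	229	247	54.5	58.9	53.3	52.6
5	Dendrobium williamsonii	Formosae	MK522234	646	163	240	243	53.3	57.7	51.3	52.3
6	Dendrobium cariniferum	Formosae	MK522238	636	163	230	243	53.8	57.7	52.2	52.7
7	Dendrobium sinense	Formosae	MK522249	638	163	228	247	53.1	58.3	53.1	49.8
8	Dendrobium jenkinsii	Chrysotoxae	MK522193	643	163	232	248	50.9	57.7	47.4	49.6
9	Dendrobium chrysotoxum	Chrysotoxae	MK522232	651	163	243	245	54.8	58.9	51.9	55.1
10	Dendrobium thyrsiflorum	Chrysotoxae	MK522235	641	164	230	247	52.6	57.3	49.1	52.6
11	Dendrobium densiflorum	Chrysotoxae	MK522257	641	163	231	247	52.7	57.1	48.9	53.4
12	Dendrobium lindleyi	Chrysotoxae	MK522261	644	163	234	247	50.5	58.9	48.3	47.0
13	Dendrobium sulcatum	Chrysotoxae	MK522262	644	163	234	247	53.7	59.5	50.9	52.6
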