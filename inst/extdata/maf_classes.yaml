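# Translation of MAF-style variant-classification spellings into the
# package's canonical vocabulary. Edit or extend for other dataset versions
# and pass the file to read_mutations(class_map = read_class_map("...")).
Missense_Mutation: missense
Nonsense_Mutation: nonsense
Frame_Shift_Del: frameshift
Frame_Shift_Ins: frameshift
Splice_Site: splice_site
In_Frame_Del: in_frame_indel
In_Frame_Ins: in_frame_indel
Nonstop_Mutation: nonstop
Translation_Start_Site: translation_start
Start_Codon_SNP: translation_start
Silent: silent
Intron: intron
5'UTR: utr5
3'UTR: utr3
5'Flank: flank
3'Flank: flank
IGR: igr
RNA: rna
# canonical labels map to themselves so pre-normalised tables round-trip
missense: missense
nonsense: nonsense
frameshift: frameshift
splice_site: splice_site
in_frame_indel: in_frame_indel
nonstop: nonstop
translation_start: translation_start
silent: silent
intron: intron
utr5: utr5
utr3: utr3
flank: flank
igr: igr
rna: rna
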