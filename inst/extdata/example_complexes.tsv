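protein_seq	nucleic_seq_1	nucleic_seq_2	dG
SANDMVLDLRETIDHWWFFE	TATGTCCT	NA	-4.93499558969455
SANDMVLDLRETIDHWWFFE	ATACTCTT	NA	-6.23288655254726
SANDMVLDLRETIDHWWFFE	GTACTAAT	NA	-6.75889529265027
SANDDSMSMIWTWHYVGRGL	GCGCTCCC	NA	-6.03936110272778
SANDDSMSMIWTWHYVGRGL	ATTTTCCA	NA	-3.44652067507822
SANDDSMSMIWTWHYVGRGL	GAGCTGCT	NA	-6.4799323262012
LCGPALVTTGYVEETVHRFR	GCGTTCCA	NA	-8.39794623621862
LCGPALVTTGYVEETVHRFR	GTCCGCGT	NA	-7.42013966109948
LCGPALVTTGYVEETVHRFR	TCAATGGT	NA	-7.75796217593657
LCGPTNGMRFVKLVESYVDN	GTTCTGAC	NA	-6.1505631526598
LCGPTNGMRFVKLVESYVDN	GTAATTAC	NA	-8.42349640137581
LCGPTNGMRFVKLVESYVDN	GTACTACG	NA	-10.5629850239518
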