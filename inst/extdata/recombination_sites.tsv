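# Recombination site table. core_start/core_end: 0-based half-open shared
# core within the site. Reversible sites (tyrosine family used with the
# recombinase alone) rejoin freely at the core; irreversible pairs (serine
# integrases, or integrase-only reactions without the excision factors)
# carry distinct markers ("." = none) for the two exchanged halves.
# loxP and FRT are the canonical published sequences; the att sites are
# representative synthetic stand-ins with the documented core layout -
# replace with your integrase's sequences for real designs.
name	sequence	core_start	core_end	reversible	partners	marker_left	marker_right
loxP	ATAACTTCGTATAATGTATGCTATACGAAGTTAT	13	21	TRUE	loxP	.	.
FRT	GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC	13	21	TRUE	FRT	.	.
phiC31_attB	GGTGCCAGGGCGTGCCCTTGGGCTCCCCGGGCGCGT	17	20	FALSE	phiC31_attP	c31x	c31y
phiC31_attP	CCCAGGTCAGAAGCGGTTTGACGGGTGTCGGGGCTG	17	20	FALSE	phiC31_attB	c31y	c31x
phiC31_attL	GGTGCCAGGGCGTGCCCTTGACGGGTGTCGGGGCTG	17	20	TRUE		.	.
phiC31_attR	CCCAGGTCAGAAGCGGTTTGGGCTCCCCGGGCGCGT	17	20	TRUE		.	.
HK022_attB	CATTAGGCACCCCAGGCTTCTACGCATCTGTGCGGT	17	20	FALSE	HK022_attP	hkx	hky
HK022_attP	GGAATTGTGAGCGGATATTCCAATTTCACACAGGAA	17	20	FALSE	HK022_attB	hky	hkx
HK022_attL	CATTAGGCACCCCAGGCTTCCAATTTCACACAGGAA	17	20	TRUE		.	.
HK022_attR	GGAATTGTGAGCGGATATTCTACGCATCTGTGCGGT	17	20	TRUE		.	.
lambda_attB	GAGCCTGCAAGTCAGTTTATACTAAGTTGAGCGTCG	15	22	FALSE	lambda_attP	lamx	lamy
lambda_attP	CAGCTTTACGCTGACTTTATACGGTAACCTACTGCT	15	22	FALSE	lambda_attB	lamy	lamx
phiBT1_attB	ACCGTGGACAGTCATGACTGGGTTCGCACTAGCCAA	17	20	FALSE	phiBT1_attP	bt1x	bt1y
phiBT1_attP	TGGCAAGCTAGCTTAACCTGCCATAGAGTCCGTTAG	17	20	FALSE	phiBT1_attB	bt1y	bt1x
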