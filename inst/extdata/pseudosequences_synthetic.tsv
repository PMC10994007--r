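allele	pseudo_sequence
HLA-A*01:01	ESCSGLCRYRMVAYSVYCHNSYVIHRASYRVTGI
HLA-A*02:01	IWYTCWWLHEEMMQYCLWNIMRDGELYIDPGPDQ
HLA-A*03:01	KQAIPEYADGCIPFMMRELTISWQDAGFYIMNAE
HLA-A*11:01	LYRDLALMLMQPHWQEMQSCENHQAPYNKPSATL
HLA-A*24:02	EIKLHFRGFAVNHMHWEHIQAVPNDNAKYPYIDA
HLA-B*07:02	GNTQEQACGYQNKEWMMDPGTMIPSDYGQWINIL
HLA-B*08:01	YGTYCRGEHCRPWQVFSKSTTSMDRDSACCTFWR
HLA-B*15:01	DVYGYIKSDMGKVDPLGTSIEEALLDKCQYCNCW
HLA-B*27:05	QFERSRVENASQKDYLNTKCITQIAQLHHRVKCV
HLA-B*40:01	TCEIKVKDWYPTQAIYSWHHICLPWWDNWWAASN
HLA-B*44:02	DYPEFYHNMMVGLKYPQSTQGLKDCFKKPSPHMD
HLA-C*03:04	SWGIVFYESPYSRDQLNHFQYSHKGKFMQCKLTA
HLA-C*04:01	TDWAQMYIKENRIYGHGCYWSHKFWQTFGNDVHT
HLA-C*07:01	QWLNQTEEGWWLLVWHTAWGITFKWNQGHICGPA
HLA-C*07:02	FYEWHRMTYANAMIGARTHWWYKMAGRSKFGQTP
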