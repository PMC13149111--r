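class	count
GTAG	149786
GCAG	1253
ATAC	185
GTTG	33
GTGG	21
ATAG	11
GAAG	9
TTAG	8
ATAA	8
ATAT	6
GGAG	6
GTAA	4
GGAC	3
GTCA	3
TGTG	2
TATC	2
GGGA	2
AGAG	2
TAGA	2
GCCC	2
GCGG	2
ACCG	1
AGTG	1
CTAG	1
GTTC	1
TGGA	1
TCAG	1
ACAC	1
GCCT	1
AGCC	1
TTCT	1
GGGC	1
CCTT	1
TCCC	1
CCCC	1
CCGG	1
CTGA	1
GATG	1
CCGT	1
GCGA	1
TGTT	1
GGAA	1
GGTC	1
GGCC	1
CTCC	1
TGTC	1
TTTT	1
AGGG	1
GGGT	1
CTAT	1
CTAA	1
CAAC	1
TCTT	1
AAGG	1
TCGG	1
GACA	1
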