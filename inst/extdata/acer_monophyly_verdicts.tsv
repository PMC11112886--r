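species	dataset	monophyletic	support
Acer amplum	plastome	Y	100
Acer amplum	matK_rbcL_trnH-psbA	Y	78
Acer amplum	nrDNA	N	NA
Acer amplum	ITS	N	NA
A. caudatum	plastome	Y	100
A. caudatum	matK_rbcL_trnH-psbA	Y	100
A. caudatum	nrDNA	Y	100
A. caudatum	ITS	Y	100
A. coriaceifolium	plastome	N	NA
A. coriaceifolium	matK_rbcL_trnH-psbA	N	NA
A. coriaceifolium	nrDNA	Y	99
A. coriaceifolium	ITS	Y	96
A. duplicatoserratum var. chinense	plastome	Y	100
A. duplicatoserratum var. chinense	matK_rbcL_trnH-psbA	Y	62
A. duplicatoserratum var. chinense	nrDNA	Y	99
A. duplicatoserratum var. chinense	ITS	Y	98
A. fabri	plastome	Y	85
A. fabri	matK_rbcL_trnH-psbA	N	NA
A. fabri	nrDNA	Y	99
A. fabri	ITS	N	NA
A. flabellatum	plastome	Y	100
A. flabellatum	matK_rbcL_trnH-psbA	N	NA
A. flabellatum	nrDNA	N	NA
A. flabellatum	ITS	N	NA
A. griseum	plastome	Y	100
A. griseum	matK_rbcL_trnH-psbA	Y	100
A. griseum	nrDNA	Y	91
A. griseum	ITS	N	NA
A. grosseri	plastome	Y	100
A. grosseri	matK_rbcL_trnH-psbA	Y	95
A. grosseri	nrDNA	Y	63
A. grosseri	ITS	Y	69
A. henryi	plastome	Y	100
A. henryi	matK_rbcL_trnH-psbA	Y	100
A. henryi	nrDNA	Y	100
A. henryi	ITS	Y	100
A. japonicum	plastome	Y	100
A. japonicum	matK_rbcL_trnH-psbA	N	NA
A. japonicum	nrDNA	N	NA
A. japonicum	ITS	N	NA
A. laurinum	plastome	Y	100
A. laurinum	matK_rbcL_trnH-psbA	Y	100
A. laurinum	nrDNA	Y	100
A. laurinum	ITS	Y	100
A. maximowiczii	plastome	Y	100
A. maximowiczii	matK_rbcL_trnH-psbA	N	NA
A. maximowiczii	nrDNA	Y	100
A. maximowiczii	ITS	Y	100
A. miaotaiense	plastome	Y	100
A. miaotaiense	matK_rbcL_trnH-psbA	Y	62
A. miaotaiense	nrDNA	Y	100
A. miaotaiense	ITS	Y	100
A. oblongum	plastome	Y	100
A. oblongum	matK_rbcL_trnH-psbA	N	NA
A. oblongum	nrDNA	Y	99
A. oblongum	ITS	Y	77
A. oliverianum	plastome	N	NA
A. oliverianum	matK_rbcL_trnH-psbA	N	NA
A. oliverianum	nrDNA	Y	100
A. oliverianum	ITS	Y	90
A. shenkanense	plastome	Y	100
A. shenkanense	matK_rbcL_trnH-psbA	Y	64
A. shenkanense	nrDNA	Y	100
A. shenkanense	ITS	Y	100
A. stachyophyllum subsp. betulifolium	plastome	Y	100
A. stachyophyllum subsp. betulifolium	matK_rbcL_trnH-psbA	Y	100
A. stachyophyllum subsp. betulifolium	nrDNA	Y	100
A. stachyophyllum subsp. betulifolium	ITS	Y	100
A. sterculiaceum subsp. franchetii	plastome	Y	100
A. sterculiaceum subsp. franchetii	matK_rbcL_trnH-psbA	Y	94
A. sterculiaceum subsp. franchetii	nrDNA	Y	100
A. sterculiaceum subsp. franchetii	ITS	N	NA
A. tataricum	plastome	Y	100
A. tataricum	matK_rbcL_trnH-psbA	Y	100
A. tataricum	nrDNA	Y	100
A. tataricum	ITS	Y	99
A. truncatum	plastome	Y	100
A. truncatum	matK_rbcL_trnH-psbA	Y	85
A. truncatum	nrDNA	Y	90
A. truncatum	ITS	Y	86
A. tutcheri	plastome	Y	100
A. tutcheri	matK_rbcL_trnH-psbA	N	NA
A. tutcheri	nrDNA	N	NA
A. tutcheri	ITS	N	NA
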