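aae|g1	aga|g1
aae|g10	aga|g10
aae|g11	aga|g11
aae|g12	ame|g12
aae|g13	aga|g13
aae|g15	aga|g15
aae|g16	aga|g16
aae|g17	aga|g17
aae|g2	aga|g2
aae|g23	aga|g23
aae|g24	ame|g24
aae|g27	aga|g27
aae|g3	aga|g3
aae|g4	aga|g4
aae|g5	aga|g5
aae|g6	aga|g6
aae|g8	aga|g8
aae|g9	aga|g9
aga|g1	ame|g1
aga|g10	ame|g10
aga|g11	ame|g11
aga|g13	ame|g13
aga|g15	ame|g15
aga|g16	ame|g16
aga|g17	ame|g17
aga|g2	ame|g2
aga|g22	ame|g22
aga|g23	cbr|g23
aga|g27	ame|g27
aga|g3	ame|g3
aga|g4	ame|g4
aga|g5	ame|g5
aga|g6	ame|g6
aga|g8	ame|g8
aga|g9	ame|g9
ame|g1	bma|g1
ame|g10	bma|g10
ame|g11	bma|g11
ame|g12	cel|g12
ame|g13	bta|g13
ame|g15	ame|g15b
ame|g15b	bta|g15
ame|g16	cqu|g16
ame|g17	cqu|g17
ame|g2	bma|g2
ame|g21	bta|g21
ame|g22	gga|g22
ame|g24	bma|g24
ame|g26	bma|g26
ame|g27	ame|g27b
ame|g27b	bma|g27
ame|g28	bma|g28
ame|g3	bma|g3
ame|g4	bma|g4
ame|g6	bma|g6
ame|g7	bma|g7
ame|g8	bma|g8
ame|g9	bma|g9
ath|g27	tad|g27
ath|g27	xtr|g27
bma|g1	bta|g1
bma|g10	bta|g10
bma|g11	cbr|g11
bma|g14	bta|g14
bma|g18	cbr|g18
bma|g19	cbr|g19
bma|g2	bta|g2
bma|g24	cbr|g24
bma|g26	bta|g26
bma|g27	bta|g27
bma|g28	bta|g28
bma|g3	bta|g3
bma|g4	bta|g4
bma|g6	bta|g6
bma|g7	bta|g7
bma|g8	bta|g8
bma|g9	bta|g9
bta|g1	cbr|g1
bta|g10	cbr|g10
bta|g13	cbr|g13
bta|g14	bta|g14b
bta|g14b	cel|g14
bta|g15	cel|g15
bta|g2	cbr|g2
bta|g20	cfa|g20
bta|g21	dre|g21
bta|g26	cbr|g26
bta|g27	cbr|g27
bta|g28	cbr|g28
bta|g3	cbr|g3
bta|g5	cbr|g5
bta|g6	cbr|g6
bta|g8	cbr|g8
bta|g9	cbr|g9
cbr|g1	cel|g1
cbr|g10	cel|g10
cbr|g11	cel|g11
cbr|g13	cel|g13
cbr|g18	cel|g18
cbr|g2	cel|g2
cbr|g23	dre|g23
cbr|g24	cin|g24
cbr|g26	cel|g26
cbr|g27	cbr|g27b
cbr|g27b	cel|g27
cbr|g28	cel|g28
cbr|g3	cel|g3
cbr|g5	cel|g5
cbr|g6	cel|g6
cbr|g8	cel|g8
cbr|g9	cel|g9
cel|g1	cfa|g1
cel|g10	cfa|g10
cel|g11	cel|g11b
cel|g11b	cfa|g11
cel|g12	dme|g12
cel|g13	cfa|g13
cel|g14	cfa|g14
cel|g15	cfa|g15
cel|g2	cfa|g2
cel|g26	cfa|g26
cel|g27	cfa|g27
cel|g28	cfa|g28
cel|g3	cfa|g3
cel|g5	cfa|g5
cel|g6	cfa|g6
cel|g7	cfa|g7
cel|g8	cel|g8b
cel|g8b	cfa|g8
cel|g9	cfa|g9
cfa|g1	cin|g1
cfa|g10	cin|g10
cfa|g11	cin|g11
cfa|g13	cin|g13
cfa|g14	cin|g14
cfa|g15	cin|g15
cfa|g2	cin|g2
cfa|g20	dre|g20
cfa|g26	cfa|g26b
cfa|g26b	cin|g26
cfa|g27	cin|g27
cfa|g28	cin|g28
cfa|g3	cin|g3
cfa|g4	cin|g4
cfa|g5	cfa|g5b
cfa|g5b	cin|g5
cfa|g6	cin|g6
cfa|g7	cin|g7
cfa|g8	cin|g8
cfa|g9	cin|g9
cin|g1	cqu|g1
cin|g10	cqu|g10
cin|g11	cqu|g11
cin|g13	cin|g13b
cin|g13b	dme|g13
cin|g14	dme|g14
cin|g15	cqu|g15
cin|g2	cqu|g2
cin|g24	dre|g24
cin|g26	cqu|g26
cin|g27	cqu|g27
cin|g28	cqu|g28
cin|g3	cqu|g3
cin|g4	cqu|g4
cin|g5	cqu|g5
cin|g6	cqu|g6
cin|g8	cqu|g8
cin|g9	cqu|g9
cqu|g1	dme|g1
cqu|g10	dme|g10
cqu|g11	dme|g11
cqu|g15	dme|g15
cqu|g16	dme|g16
cqu|g2	dme|g2
cqu|g26	dme|g26
cqu|g27	dme|g27
cqu|g3	dme|g3
cqu|g4	dme|g4
cqu|g5	dme|g5
cqu|g6	dme|g6
cqu|g8	cqu|g8b
cqu|g8b	dme|g8
cqu|g9	dme|g9
dme|g1	dps|g1
dme|g10	dps|g10
dme|g11	dps|g11
dme|g12	dps|g12
dme|g13	gga|g13
dme|g14	dps|g14
dme|g15	dps|g15
dme|g16	dps|g16
dme|g2	dme|g2b
dme|g26	dps|g26
dme|g27	dps|g27
dme|g2b	dps|g2
dme|g3	dps|g3
dme|g4	dps|g4
dme|g5	dps|g5
dme|g6	dme|g6b
dme|g6b	dps|g6
dme|g7	dps|g7
dme|g8	dps|g8
dme|g9	dps|g9
dps|g1	dre|g1
dps|g10	dre|g10
dps|g11	hsa|g11
dps|g12	gga|g12
dps|g14	dre|g14
dps|g15	dre|g15
dps|g16	nvi|g16
dps|g17	nvi|g17
dps|g2	dre|g2
dps|g26	dre|g26
dps|g27	dre|g27
dps|g28	dre|g28
dps|g3	dre|g3
dps|g4	dre|g4
dps|g5	dre|g5
dps|g6	dre|g6
dps|g7	dre|g7
dps|g8	dre|g8
dps|g9	dre|g9
dre|g1	gga|g1
dre|g10	gga|g10
dre|g14	gga|g14
dre|g15	gga|g15
dre|g2	gga|g2
dre|g20	gga|g20
dre|g21	tni|g21
dre|g24	mdo|g24
dre|g26	gga|g26
dre|g28	gga|g28
dre|g3	gga|g3
dre|g5	gga|g5
dre|g6	gga|g6
dre|g7	gga|g7
dre|g8	gga|g8
dre|g9	gga|g9
gga|g1	hsa|g1
gga|g10	hsa|g10
gga|g12	hsa|g12
gga|g13	hsa|g13
gga|g14	hsa|g14
gga|g15	hsa|g15
gga|g2	hsa|g2
gga|g20	hsa|g20
gga|g22	mdo|g22
gga|g26	hsa|g26
gga|g28	gga|g28b
gga|g28b	hsa|g28
gga|g3	hsa|g3
gga|g5	hsa|g5
gga|g6	hsa|g6
gga|g7	hsa|g7
gga|g8	hsa|g8
gga|g9	hsa|g9
hsa|g1	hsa|g1b
hsa|g10	mdo|g10
hsa|g11	mdo|g11
hsa|g12	nve|g12
hsa|g13	mdo|g13
hsa|g14	mmu|g14
hsa|g15	mdo|g15
hsa|g1b	mdo|g1
hsa|g2	mdo|g2
hsa|g20	mdo|g20
hsa|g26	mdo|g26
hsa|g27	mdo|g27
hsa|g28	mdo|g28
hsa|g3	mdo|g3
hsa|g4	mdo|g4
hsa|g5	mdo|g5
hsa|g6	mdo|g6
hsa|g7	mdo|g7
hsa|g8	mdo|g8
hsa|g9	mdo|g9
mdo|g1	mdo|g1b
mdo|g10	mdo|g10b
mdo|g10b	mmu|g10
mdo|g11	mdo|g11b
mdo|g13	mmu|g13
mdo|g15	nve|g15
mdo|g1b	mmu|g1
mdo|g2	mmu|g2
mdo|g20	mdo|g20b
mdo|g20b	mmu|g20
mdo|g22	mdo|g22b
mdo|g24	nve|g24
mdo|g26	mmu|g26
mdo|g27	mmu|g27
mdo|g28	mmu|g28
mdo|g3	mmu|g3
mdo|g5	mmu|g5
mdo|g6	mmu|g6
mdo|g7	mmu|g7
mdo|g8	mmu|g8
mdo|g9	mmu|g9
mmu|g1	nve|g1
mmu|g10	nve|g10
mmu|g13	nve|g13
mmu|g14	nvi|g14
mmu|g2	mmu|g2b
mmu|g20	rno|g20
mmu|g26	nve|g26
mmu|g27	nve|g27
mmu|g28	nve|g28
mmu|g2b	nve|g2
mmu|g3	nve|g3
mmu|g5	nve|g5
mmu|g6	nve|g6
mmu|g8	nve|g8
nve|g1	nvi|g1
nve|g10	nvi|g10
nve|g12	nvi|g12
nve|g13	phu|g13
nve|g15	nvi|g15
nve|g2	nvi|g2
nve|g24	nve|g24b
nve|g24b	nvi|g24
nve|g27	nvi|g27
nve|g28	nvi|g28
nve|g3	nvi|g3
nve|g4	nvi|g4
nve|g5	nvi|g5
nve|g6	nvi|g6
nve|g8	nvi|g8
nvi|g1	phu|g1
nvi|g10	phu|g10
nvi|g12	phu|g12
nvi|g14	phu|g14
nvi|g15	rno|g15
nvi|g16	phu|g16
nvi|g17	phu|g17
nvi|g2	nvi|g2b
nvi|g22	tni|g22
nvi|g24	phu|g24
nvi|g27	phu|g27
nvi|g28	phu|g28
nvi|g2b	phu|g2
nvi|g3	phu|g3
nvi|g4	phu|g4
nvi|g7	phu|g7
nvi|g8	phu|g8
phu|g1	rno|g1
phu|g10	rno|g10
phu|g12	tad|g12
phu|g13	xtr|g13
phu|g14	phu|g14b
phu|g14b	rno|g14
phu|g2	rno|g2
phu|g24	phu|g24b
phu|g24b	tni|g24
phu|g26	rno|g26
phu|g27	rno|g27
phu|g28	phu|g28b
phu|g28b	rno|g28
phu|g4	rno|g4
phu|g7	rno|g7
phu|g8	rno|g8
phu|g9	rno|g9
rno|g1	tad|g1
rno|g10	tni|g10
rno|g11	tad|g11
rno|g14	tni|g14
rno|g15	tni|g15
rno|g2	tad|g2
rno|g20	rno|g20b
rno|g26	tad|g26
rno|g27	tad|g27
rno|g28	rno|g28b
rno|g28b	tad|g28
rno|g4	tad|g4
rno|g5	tad|g5
rno|g6	tni|g6
rno|g7	tad|g7
rno|g8	tad|g8
rno|g9	tni|g9
tad|g1	tni|g1
tad|g11	tru|g11
tad|g12	xtr|g12
tad|g2	tni|g2
tad|g26	tni|g26
tad|g27	tni|g27
tad|g28	tad|g28b
tad|g28b	tni|g28
tad|g3	tni|g3
tad|g4	tni|g4
tad|g5	tni|g5
tad|g7	tni|g7
tad|g8	tni|g8
tni|g1	tru|g1
tni|g10	tru|g10
tni|g15	xtr|g15
tni|g2	tru|g2
tni|g21	tru|g21
tni|g22	tru|g22
tni|g24	tru|g24
tni|g26	tru|g26
tni|g27	tru|g27
tni|g28	tru|g28
tni|g3	tni|g3b
tni|g3b	tru|g3
tni|g4	tru|g4
tni|g5	tru|g5
tni|g6	tru|g6
tni|g7	tru|g7
tni|g8	tni|g8b
tni|g8b	tru|g8
tni|g9	tni|g9b
tni|g9b	tru|g9
tru|g1	xtr|g1
tru|g10	xtr|g10
tru|g2	xtr|g2
tru|g20	xtr|g20
tru|g21	tru|g21b
tru|g26	xtr|g26
tru|g27	xtr|g27
tru|g28	xtr|g28
tru|g3	xtr|g3
tru|g4	xtr|g4
tru|g5	xtr|g5
tru|g6	xtr|g6
tru|g7	xtr|g7
tru|g8	xtr|g8
tru|g9	xtr|g9
xtr|g1	xtr|g1b
xtr|g12	xtr|g12b
xtr|g13	xtr|g13b
xtr|g26	xtr|g26b
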