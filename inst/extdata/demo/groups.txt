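OG00001: aae|g1 aga|g1 ame|g1 bma|g1 bta|g1 cbr|g1 cel|g1 cfa|g1 cin|g1 cqu|g1 dme|g1 dps|g1 dre|g1 gga|g1 hsa|g1 hsa|g1b mdo|g1 mdo|g1b mmu|g1 nve|g1 nvi|g1 phu|g1 rno|g1 tad|g1 tni|g1 tru|g1 xtr|g1 xtr|g1b
OG00002: aae|g2 aga|g2 ame|g2 bma|g2 bta|g2 cbr|g2 cel|g2 cfa|g2 cin|g2 cqu|g2 dme|g2 dme|g2b dps|g2 dre|g2 gga|g2 hsa|g2 mdo|g2 mmu|g2 mmu|g2b nve|g2 nvi|g2 nvi|g2b phu|g2 rno|g2 tad|g2 tni|g2 tru|g2 xtr|g2
OG00003: aae|g3 aga|g3 ame|g3 bma|g3 bta|g3 cbr|g3 cel|g3 cfa|g3 cin|g3 cqu|g3 dme|g3 dps|g3 dre|g3 gga|g3 hsa|g3 mdo|g3 mmu|g3 nve|g3 nvi|g3 phu|g3 tad|g3 tni|g3 tni|g3b tru|g3 xtr|g3
OG00004: aae|g4 aga|g4 ame|g4 bma|g4 bta|g4 cfa|g4 cin|g4 cqu|g4 dme|g4 dps|g4 dre|g4 hsa|g4 mdo|g4 nve|g4 nvi|g4 phu|g4 rno|g4 tad|g4 tni|g4 tru|g4 xtr|g4
OG00005: aae|g5 aga|g5 ame|g5 bta|g5 cbr|g5 cel|g5 cfa|g5 cfa|g5b cin|g5 cqu|g5 dme|g5 dps|g5 dre|g5 gga|g5 hsa|g5 mdo|g5 mmu|g5 nve|g5 nvi|g5 rno|g5 tad|g5 tni|g5 tru|g5 xtr|g5
OG00006: aae|g6 aga|g6 ame|g6 bma|g6 bta|g6 cbr|g6 cel|g6 cfa|g6 cin|g6 cqu|g6 dme|g6 dme|g6b dps|g6 dre|g6 gga|g6 hsa|g6 mdo|g6 mmu|g6 nve|g6 nvi|g6 rno|g6 tni|g6 tru|g6 xtr|g6
OG00007: ame|g7 bma|g7 bta|g7 cel|g7 cfa|g7 cin|g7 dme|g7 dps|g7 dre|g7 gga|g7 hsa|g7 mdo|g7 mmu|g7 nvi|g7 phu|g7 rno|g7 tad|g7 tni|g7 tru|g7 xtr|g7
OG00008: aae|g8 aga|g8 ame|g8 bma|g8 bta|g8 cbr|g8 cel|g8 cel|g8b cfa|g8 cin|g8 cqu|g8 cqu|g8b dme|g8 dps|g8 dre|g8 gga|g8 hsa|g8 mdo|g8 mmu|g8 nve|g8 nvi|g8 phu|g8 rno|g8 tad|g8 tni|g8 tni|g8b tru|g8 xtr|g8
OG00009: aae|g9 aga|g9 ame|g9 bma|g9 bta|g9 cbr|g9 cel|g9 cfa|g9 cin|g9 cqu|g9 dme|g9 dps|g9 dre|g9 gga|g9 hsa|g9 mdo|g9 mmu|g9 phu|g9 rno|g9 tni|g9 tni|g9b tru|g9 xtr|g9
OG00010: aae|g10 aga|g10 ame|g10 bma|g10 bta|g10 cbr|g10 cel|g10 cfa|g10 cin|g10 cqu|g10 dme|g10 dps|g10 dre|g10 gga|g10 hsa|g10 mdo|g10 mdo|g10b mmu|g10 nve|g10 nvi|g10 phu|g10 rno|g10 tni|g10 tru|g10 xtr|g10
OG00011: aae|g11 aga|g11 ame|g11 ath|g11 bma|g11 cbr|g11 cel|g11 cel|g11b cfa|g11 cin|g11 cqu|g11 ddi|g11 dme|g11 dps|g11 hsa|g11 mbr|g11 mdo|g11 mdo|g11b nm001|g11 nm003|g11 rno|g11 sce|g11 spo|g11 spo|g11b tad|g11 tgo|g11 tru|g11
OG00012: aae|g12 ame|g12 ath|g12 cel|g12 ddi|g12 dme|g12 dps|g12 gga|g12 hsa|g12 mbr|g12 nm001|g12 nm003|g12 nve|g12 nvi|g12 osa|g12 phu|g12 spo|g12 tad|g12 tgo|g12 xtr|g12 xtr|g12b
OG00013: aae|g13 aga|g13 ame|g13 bta|g13 cbr|g13 cel|g13 cfa|g13 cin|g13 cin|g13b ddi|g13 dme|g13 gga|g13 hsa|g13 mbr|g13 mdo|g13 mmu|g13 nm001|g13 nm003|g13 nve|g13 pfa|g13 phu|g13 sce|g13 tgo|g13 xtr|g13 xtr|g13b
OG00014: ath|g14 bma|g14 bta|g14 bta|g14b cel|g14 cfa|g14 cin|g14 ddi|g14 dme|g14 dps|g14 dre|g14 gga|g14 hsa|g14 mmu|g14 nm001|g14 nm001|g14b nm003|g14 nvi|g14 osa|g14 pfa|g14 phu|g14 phu|g14b rno|g14 sce|g14 spo|g14 tgo|g14 tni|g14
OG00015: aae|g15 aga|g15 ame|g15 ame|g15b ath|g15 bta|g15 cel|g15 cfa|g15 cin|g15 cqu|g15 ddi|g15 dme|g15 dps|g15 dre|g15 gga|g15 hsa|g15 mdo|g15 nm003|g15 nve|g15 nvi|g15 rno|g15 sce|g15 spo|g15 tgo|g15 tni|g15 xtr|g15
OG00016: aae|g16 aga|g16 ame|g16 cqu|g16 dme|g16 dps|g16 nvi|g16 phu|g16
OG00017: aae|g17 aga|g17 ame|g17 cqu|g17 dps|g17 nvi|g17 phu|g17
OG00018: bma|g18 cbr|g18 cel|g18
OG00019: bma|g19 cbr|g19
OG00020: bta|g20 cfa|g20 dre|g20 gga|g20 hsa|g20 mdo|g20 mdo|g20b mmu|g20 rno|g20 rno|g20b tru|g20 xtr|g20
OG00021: ame|g21 ath|g21 ath|g21b bsu|g21 bta|g21 dre|g21 nm001|g21 osa|g21 spo|g21 spo|g21b tni|g21 tru|g21 tru|g21b
OG00022: aga|g22 ame|g22 ath|g22 ddi|g22 gga|g22 mbr|g22 mdo|g22 mdo|g22b nm001|g22 nm003|g22 nm003|g22b nm004|g22 nvi|g22 tni|g22 tru|g22
OG00023: aae|g23 aga|g23 bsu|g23 cbr|g23 ddi|g23 dre|g23 eco|g23 mbr|g23 nm002|g23 nm004|g23 osa|g23 pfa|g23 spo|g23 tgo|g23
OG00024: aae|g24 ame|g24 ath|g24 bma|g24 cbr|g24 cin|g24 ddi|g24 dre|g24 eco|g24 mbr|g24 mdo|g24 nm003|g24 nm004|g24 nve|g24 nve|g24b nvi|g24 osa|g24 pfa|g24 phu|g24 phu|g24b sce|g24 tgo|g24 tni|g24 tru|g24
OG00025: ath|g25 eco|g25 nm001|g25 nm001|g25b nm003|g25 osa|g25 tgo|g25
OG00026: aae|g26 ame|g26 bma|g26 bta|g26 cbr|g26 cel|g26 cfa|g26 cfa|g26b cin|g26 cqu|g26 dme|g26 dps|g26 dre|g26 gga|g26 hsa|g26 mdo|g26 mmu|g26 nve|g26 phu|g26 rno|g26 tad|g26 tgo|g26 tni|g26 tru|g26 xtr|g26 xtr|g26b
OG00027: aae|g27 aga|g27 ame|g27 ame|g27b ath|g27 ath|g27b bma|g27 bta|g27 cbr|g27 cbr|g27b cel|g27 cfa|g27 cin|g27 cqu|g27 dme|g27 dps|g27 dre|g27 hsa|g27 mdo|g27 mmu|g27 nve|g27 nvi|g27 phu|g27 rno|g27 tad|g27 tni|g27 tru|g27 xtr|g27
OG00028: aae|g28 ame|g28 bma|g28 bta|g28 cbr|g28 cel|g28 cfa|g28 cin|g28 cqu|g28 dps|g28 dre|g28 gga|g28 gga|g28b hsa|g28 mdo|g28 mmu|g28 nve|g28 nvi|g28 phu|g28 phu|g28b rno|g28 rno|g28b spo|g28 tad|g28 tad|g28b tni|g28 tru|g28 xtr|g28
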