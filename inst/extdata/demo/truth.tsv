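group_id	class	focal_present	n_foreign_species	max_foreign_links
OG00001	metazoan_core	true	0	0
OG00002	metazoan_core	true	0	0
OG00003	metazoan_core	true	0	0
OG00004	metazoan_core	true	0	0
OG00005	metazoan_core	true	0	0
OG00006	metazoan_core	false	0	0
OG00007	metazoan_core	true	0	0
OG00008	metazoan_core	true	0	0
OG00009	eumetazoan_core_no_focal	false	0	0
OG00010	eumetazoan_core_no_focal	false	0	0
OG00011	eukaryote_core	true	0	0
OG00012	eukaryote_core	true	0	0
OG00013	eukaryote_core	false	0	0
OG00014	eukaryote_core	false	0	0
OG00015	eukaryote_core	false	0	0
OG00016	clade_restricted	false	0	0
OG00017	clade_restricted	false	0	0
OG00018	clade_restricted	false	0	0
OG00019	clade_restricted	false	0	0
OG00020	clade_restricted	false	0	0
OG00021	promiscuous	false	0	0
OG00022	promiscuous	false	0	0
OG00023	promiscuous	false	0	0
OG00024	promiscuous	false	0	0
OG00025	promiscuous	false	0	0
OG00026	contaminated_metazoan	true	1	0
OG00027	contaminated_metazoan	true	1	2
OG00028	contaminated_metazoan	true	1	0
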