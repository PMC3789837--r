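clade_members.Arthropoda=dme,dps,aga,aae,cqu,ame,nvi,phu
clade_members.Cnidaria=nve
clade_members.Craniata=hsa,mmu,rno,cfa,bta,gga,xtr,dre,tni,tru,mdo
clade_members.Nematoda=cel,cbr,bma
clade_members.Urochordata=cin
clade_min_presence.Craniata=9
clade_min_presence.Arthropoda=6
clade_min_presence.Nematoda=2
alternative_representatives=cin,nve
counted_metazoans=hsa,mmu,rno,cfa,bta,gga,xtr,dre,tni,tru,mdo,cin,dme,dps,aga,aae,cqu,ame,nvi,phu,cel,cbr,bma,nve
total_min_presence=20
focal_species=tad
nonmetazoan_counted=sce,spo,ath,osa,ddi,mbr,pfa,tgo,eco,bsu,nm001,nm002,nm003,nm004
max_foreign_species=2
max_foreign_rbbh_links=3
control_required_species=hsa,cel,dme,sce,ath
control_forbidden_species=eco,bsu,nm002,nm004
species_universe=hsa,mmu,rno,cfa,bta,gga,xtr,dre,tni,tru,mdo,cin,dme,dps,aga,aae,cqu,ame,nvi,phu,cel,cbr,bma,nve,tad,sce,spo,ath,osa,ddi,mbr,pfa,tgo,eco,bsu,nm001,nm002,nm003,nm004,nm005
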