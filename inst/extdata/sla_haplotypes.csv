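haplotype_id,class1_id,class2_id,sla1_alleles,sla3_allele,sla2_allele,drb1_allele,dqb1_allele,recombinant,dam_count,sire_count
6.7,6.0,0.7,SLA-1*08:05,SLA-3*06:01,SLA-2*05:04,DRB1*06:01,DQB1*06:01,FALSE,9,0
10.11,10.0,0.11,SLA-1*05:01,SLA-3*08:01,SLA-2*03:02,DRB1*09:01,DQB1*04:02,FALSE,102,79
16.16,16.0,0.16,SLA-1*04:01,SLA-3*06:02,SLA-2*09:01,DRB1*11:03,DQB1*06:01,FALSE,83,87
17.17,17.0,0.17,SLA-1*08:04,SLA-3*03:05,SLA-2*06:03,DRB1*08:01,DQB1*05:01,FALSE,179,102
20.18,20.0,0.18,SLA-1*10:02,SLA-3*01:01,SLA-2*11:01:02,DRB1*14:01,DQB1*04:01:02,FALSE,144,59
31.13,31.0,0.13,SLA-1*15:02,SLA-3*07:01:02,SLA-2*16:01,DRB1*04:03,DQB1*03:03,FALSE,63,31
35.23,35.0,0.23,SLA-1*12:01;SLA-1*13:01,SLA-3*05:02,SLA-2*10:01,DRB1*10:01,DQB1*06:01,FALSE,353,536
43.37,43.0,0.37,SLA-1*11:04,SLA-3*04:01,SLA-2*04:02:02,DRB1*07:01,DQB1*05:02,FALSE,300,288
10.23,10.0,0.23,SLA-1*05:01,SLA-3*08:01,SLA-2*03:02,DRB1*10:01,DQB1*06:01,TRUE,0,0
35.17,35.0,0.17,SLA-1*12:01;SLA-1*13:01,SLA-3*05:02,SLA-2*10:01,DRB1*08:01,DQB1*05:01,TRUE,35,111
43.17,43.0,0.17,SLA-1*11:04,SLA-3*04:01,SLA-2*04:02:02,DRB1*08:01,DQB1*05:01,TRUE,32,7
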