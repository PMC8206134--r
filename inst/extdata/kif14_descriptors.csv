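group,nucleotide,mt_bound,d_sw1_pl,d_kh0_sw2,beta_twist,neck_linker,model,pdb_id
semi_closed,ADP,no,13.4,21.4,45.8,"Undocked, mobile",K-ADP,4OZQ
open,ADP,yes,14.3,24.9,44.6,"Undocked, mobile",MT-K743-ADP,6WWQ
open,ADP,yes,14.8,23.7,42.8,"Undocked, mobile",MT-K748-ADP,6WWM
open,ADP,yes,14.4,24.5,46.0,"Undocked, sideways",MT-K755-ADP,6WWJ
open,ADP,yes,14.8,22.4,42.2,"Undocked, sideways",MT-K772-ADP,6WWF
open,Apo,yes,14.7,23.0,45.4,Not present,MT-K735-Apo,6WWT
open,Apo,yes,14.1,23.6,42.7,"Undocked, mobile",MT-K743-Apo,6WWP
open,Apo,yes,14.6,24.9,44.4,"Undocked, sideways",MT-K755-Apo,6WWI
open,Apo,yes,15.2,25.4,41.8,"Undocked, sideways",MT-K772-Apo,6WWE
open_star,AMP-PNP,yes,14.2,20.9,44.0,Not present,MT-K735-ANP,6WWV
open_star,AMP-PNP,yes,14.3,24.2,45.6,"Undocked, mobile",MT-K743-ANP-O,6WWS
open_star,AMP-PNP,yes,14.3,24.4,44.1,"Undocked, backwards",MT-K755-ANP-L,6WWL
open_star,AMP-PNP,yes,14.0,22.2,43.3,"Undocked, backwards",MT-K772-ANP-L,6WWH
open_star,ADP-AlFx,yes,14.4,23.5,42.6,Not present,MT-K735-AAF,6WWU
open_star,ADP-AlFx,yes,14.3,23.8,45.1,"Undocked, mobile",MT-K743-AAF-O,6WWR
open_star,ADP-AlFx,yes,14.8,22.8,44.0,"Undocked, backwards",MT-K755-AAF-L,6WWK
open_star,ADP-AlFx,yes,14.5,21.8,44.7,"Undocked, backwards",MT-K772-AAF-L,6WWG
closed,AMP-PNP,yes,12.7,12.0,36.4,Docked,MT-K743-ANP-C,7LVQ
closed,AMP-PNP,yes,12.8,11.2,37.2,Docked,MT-K748-ANP,6WWO
closed,AMP-PNP,yes,12.3,11.0,36.4,"Docked, partially unzipped",MT-K755-ANP-T,6WWL
closed,AMP-PNP,yes,12.3,13.0,35.0,"Docked, partially unzipped",MT-K772-ANP-T,6WWH
closed,ADP-AlFx,yes,13.1,11.2,33.7,Docked,MT-K743-AAF-C,7LVR
closed,ADP-AlFx,yes,12.4,11.6,35.4,Docked,MT-K748-AAF,6WWN
closed,ADP-AlFx,yes,11.9,11.9,37.0,"Docked, partially unzipped",MT-K755-AAF-T,6WWK
closed,ADP-AlFx,yes,12.8,11.4,36.7,"Docked, partially unzipped",MT-K772-AAF-T,6WWG
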