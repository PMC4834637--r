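fc_id,lat1,region1,gyral1,ba1,net1,lat2,region2,gyral2,ba2,net2,r_td,r_asd,weight
1,R,Diagonal ramus of the lateral fissure,Inferior frontal gyrus,44,SM,R,Ascending ramus of the lateral fissure,Inferior frontal gyrus,45,CO,0.77,0.71,-0.88
2,R,Subcallosal sulcus,Middle cingulum,23,DM,R,Calloso-marginal posterior fissure,Middle cingulum,23,CO,0.39,0.22,-1.95
3,R,Thalamus,Thalamus,NA,CO,L,Subcallosal sulcus,Posterior cingulum,29,DM,0.30,0.10,-2.62
4,R,Amygdala,Amygdala,34,CO,L,Accumbens,Caudate,NA,CO,0.16,0.05,-2.14
5,R,Rhinal sulcus,Parahippocampal gyrus,30,CO,R,Olfactory sulcus,Rectus,11,DM,0.11,-0.04,-2.11
6,R,Median occipito-temporal lateral sulcus,Inferior temporal gyrus,20,CO,L,Anterior inferior frontal sulcus,Inferior frontal gyrus,45,FP,0.03,-0.01,-0.98
7,R,Posterior terminal ascending branch of the superior temporal sulcus,Middle temporal gyrus,21,DM,R,Internal occipito-temporal lateral sulcus,Fusiform,37,OC,-0.09,-0.21,-1.26
8,R,Intermediate precentral sulcus,Middle frontal gyrus,46,FP,L,Occipital lobe,Middle occipital gyrus,19,OC,-0.10,-0.19,-1.59
9,L,Polar frontal sulcus,Superior frontal gyrus,9,DM,R,Retro central transverse ramus of the lateral fissure,Postcentral gyrus,3,SM,-0.16,-0.29,-1.52
10,R,Caudate,Caudate,NA,CO,L,Calloso-marginal anterior fissure,Anterior cingulum,32,CO,0.17,0.22,0.76
11,R,Olfactory sulcus,Rectus,11,DM,L,Parieto-occipital fissure,Cuneus,18,DM,-0.10,-0.02,1.78
12,L,Pallidum,Pallidum,NA,CO,R,Superior temporal sulcus,Superior temporal gyrus,22,CO,-0.14,0.04,1.90
13,M,Vermis,Vermis,NA,CB,R,Superior temporal sulcus,Superior temporal gyrus,22,CO,-0.18,-0.04,1.85
14,L,Superior parietal sulcus,Superior parietal gyrus,7,FP,R,Anterior lateral fissure,Inferior frontal gyrus,47,CO,-0.19,-0.06,0.99
15,R,Inferior precentral sulcus,Inferior frontal gyrus,44,SM,R,Parieto-occipital fissure,Cuneus,18,OC,-0.24,-0.13,1.00
16,L,Anterior inferior frontal sulcus,Inferior frontal gyrus,45,FP,R,Calcarine fissure,Calcarine,17,OC,-0.24,-0.16,1.74
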