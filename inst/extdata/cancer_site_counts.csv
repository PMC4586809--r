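system,site,count
digestive,Gum and mouth,506
digestive,Esophagus,7745
digestive,Stomach,14190
digestive,Small intestine,4183
digestive,Colon and rectum,85821
digestive,Anus and anal canal and anorectum,2876
digestive,Liver,14032
digestive,Gallbladder,2095
digestive,Other biliary,2702
digestive,Pancreas,19124
digestive,Retroperitoneum,780
digestive,"Peritoneum, omentum and mesentery",1026
digestive,Other digestive organs,572
respiratory,"Nose, nasal cavity and middle ear",1469
respiratory,Larynx,7720
respiratory,Lung and bronchus,113357
respiratory,Pleura,1295
respiratory,"Trachea, mediastinum and other respiratory organs",596
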