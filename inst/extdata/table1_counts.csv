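variable,category,count,n,percent_printed,printed_consistent
other_atopic_disorders,A-AD,25,25,100,1
other_atopic_disorders,NA,72,186,39,1
other_atopic_disorders,NA-AD,72,72,100,1
allergic_rhinitis,A-AD,23,25,92,1
allergic_rhinitis,NA,47,186,25,1
allergic_rhinitis,NA-AD,47,72,65,1
atopic_dermatitis,A-AD,8,25,32,1
atopic_dermatitis,NA,12,186,6,1
atopic_dermatitis,NA-AD,12,72,17,1
allergic_conjunctivitis,A-AD,17,25,68,1
allergic_conjunctivitis,NA,26,186,14,1
allergic_conjunctivitis,NA-AD,26,72,36,1
food_allergy,A-AD,5,25,20,1
food_allergy,NA,10,186,5,1
food_allergy,NA-AD,10,72,14,1
drug_allergy,A-AD,5,25,20,1
drug_allergy,NA,14,186,8,1
drug_allergy,NA-AD,14,72,19,1
parental_asthma,A-AD,6,25,24,1
parental_asthma,NA,11,186,6,1
parental_asthma,NA-AD,6,72,8,1
parental_asthma,NA-NAD,5,114,4,1
parental_rhinitis,A-AD,10,25,40,1
parental_rhinitis,NA,36,186,19,1
parental_rhinitis,NA-AD,21,72,29,1
parental_rhinitis,NA-NAD,15,114,13,1
parental_dermatitis,A-AD,3,25,12,1
parental_dermatitis,NA,8,186,4,1
parental_dermatitis,NA-AD,2,72,3,1
parental_dermatitis,NA-NAD,6,114,5,1
antibiotics,A-AD,11,25,44,1
antibiotics,NA,57,186,31,1
antibiotics,NA-AD,22,72,31,1
antibiotics,NA-NAD,35,114,31,1
paracetamol,A-AD,18,25,72,1
paracetamol,NA,107,186,56,0
paracetamol,NA-AD,39,72,54,1
paracetamol,NA-NAD,68,114,60,1
inhaled_corticosteroids,A-AD,2,25,8,1
inhaled_corticosteroids,NA,5,186,3,1
inhaled_corticosteroids,NA-AD,3,72,4,1
inhaled_corticosteroids,NA-NAD,2,114,2,1
injectable_corticosteroids,A-AD,2,25,8,1
injectable_corticosteroids,NA,7,186,4,1
injectable_corticosteroids,NA-AD,6,72,8,1
injectable_corticosteroids,NA-NAD,1,114,1,1
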