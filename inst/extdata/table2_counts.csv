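variable,category,count,n,percent_printed,printed_consistent
other_atopic_disorders,A-AD,14,14,100,1
other_atopic_disorders,NA,47,111,42,1
other_atopic_disorders,NA-AD,47,47,100,1
allergic_rhinitis,A-AD,14,14,100,1
allergic_rhinitis,NA,34,111,31,1
allergic_rhinitis,NA-AD,34,47,72,1
atopic_dermatitis,A-AD,5,14,36,1
atopic_dermatitis,NA,13,111,12,1
atopic_dermatitis,NA-AD,13,47,28,1
allergic_conjunctivitis,A-AD,8,14,57,1
allergic_conjunctivitis,NA,20,111,18,1
allergic_conjunctivitis,NA-AD,20,47,43,1
food_allergy,A-AD,1,14,7,1
food_allergy,NA,7,111,6,1
food_allergy,NA-AD,7,47,15,1
drug_allergy,A-AD,3,14,21,1
drug_allergy,NA,8,111,7,1
drug_allergy,NA-AD,8,47,17,1
parental_asthma,A-AD,3,14,21,1
parental_asthma,NA,12,111,11,1
parental_asthma,NA-AD,5,47,11,1
parental_asthma,NA-NAD,7,64,11,1
parental_rhinitis,A-AD,7,14,50,1
parental_rhinitis,NA,34,111,31,1
parental_rhinitis,NA-AD,19,47,40,1
parental_rhinitis,NA-NAD,15,64,23,1
parental_dermatitis,A-AD,2,14,14,1
parental_dermatitis,NA,11,111,10,1
parental_dermatitis,NA-AD,6,47,13,1
parental_dermatitis,NA-NAD,5,64,8,1
antibiotics,A-AD,1,14,7,1
antibiotics,NA,32,111,29,1
antibiotics,NA-AD,12,47,26,1
antibiotics,NA-NAD,20,64,31,1
paracetamol,A-AD,8,14,57,1
paracetamol,NA,67,111,60,1
paracetamol,NA-AD,31,47,66,1
paracetamol,NA-NAD,36,64,56,1
inhaled_corticosteroids,A-AD,2,14,14,1
inhaled_corticosteroids,NA,1,111,1,1
inhaled_corticosteroids,NA-AD,1,47,2,1
inhaled_corticosteroids,NA-NAD,0,64,0,1
injectable_corticosteroids,A-AD,0,14,0,1
injectable_corticosteroids,NA,2,111,2,1
injectable_corticosteroids,NA-AD,1,47,2,1
injectable_corticosteroids,NA-NAD,1,64,2,1
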