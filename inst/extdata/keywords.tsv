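lisinopril	drug
metformin	drug
xanax	drug
prozac	drug
zoloft	drug
lipitor	drug
insulin	drug
aspirin	drug
tylenol	drug
advil	drug
concerta	drug
vyvanse	drug
plavix	drug
diovan	drug
valium	drug
adderall	drug
#bcsm	hashtag
#hcsm	hashtag
#meded	hashtag
#mhsm	hashtag
aids	disorder
asthma	disorder
diabetes	disorder
cancer	disorder
depression	disorder
migraine	disorder
headache	disorder
stroke	disorder
arthritis	disorder
adhd	disorder
flu	disorder
anemia	disorder
heart attack	disorder
high blood pressure	disorder
novartis	pharma
pfizer	pharma
merck	pharma
aetna	insurance
cigna	insurance
humana	insurance
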