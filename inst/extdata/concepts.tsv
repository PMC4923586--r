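C0027051	Myocardial infarction	MI|myocardial infarction|heart attack	Disorders
C0018681	Headache	headache|headaches|cephalalgia	Disorders
C0011849	Diabetes mellitus	diabetes|diabetes mellitus	Disorders
C0004096	Asthma	asthma	Disorders
C0011570	Depression	depression|depressed mood	Disorders
C0003123	Anorexia	anorexia	Disorders
C0020538	Hypertension	hypertension|high blood pressure	Disorders
C0002395	Alzheimer disease	alzheimer|alzheimers disease	Disorders
C0006826	Cancer	cancer|malignant tumor	Disorders
C0011847	Diabetic	diabetic	Disorders
C0015967	Fever	fever|pyrexia	Disorders
C0026769	Multiple sclerosis	multiple sclerosis|ms disorder	Disorders
C0004352	Autism	autism	Disorders
C1263846	ADHD	adhd|attention deficit hyperactivity disorder	Disorders
C0011991	Diarrhea	diarrhea	Disorders
C0021400	Influenza	influenza|flu	Disorders
C0023890	Cirrhosis	cirrhosis	Disorders
C0038436	Stroke	stroke|cerebrovascular accident	Disorders
C0003864	Arthritis	arthritis	Disorders
C0010054	Coronary arteriosclerosis	coronary arteriosclerosis	Disorders
C0019158	Hepatitis	hepatitis	Disorders
C0033975	Psychosis	psychosis	Disorders
C0036341	Schizophrenia	schizophrenia	Disorders
C0011253	Dementia	dementia	Disorders
C0027497	Nausea	nausea	Disorders
C0004238	Atrial fibrillation	atrial fibrillation	Disorders
C0002871	Anemia	anemia	Disorders
C0149931	Migraine	migraine|migraines	Disorders
C0030193	Pain	pain|ache	Disorders
C0022104	Irritable bowel syndrome	irritable bowel syndrome|ibs	Disorders
C0699142	Tylenol	tylenol	Chemicals & Drugs
C0593507	Advil	advil	Chemicals & Drugs
C0699203	Motrin	motrin	Chemicals & Drugs
C0065374	Lisinopril	lisinopril	Chemicals & Drugs
C0728762	Xanax	xanax	Chemicals & Drugs
C0724441	Prozac	prozac	Chemicals & Drugs
C0678180	Zoloft	zoloft	Chemicals & Drugs
C0025598	Metformin	metformin	Chemicals & Drugs
C0593906	Lipitor	lipitor	Chemicals & Drugs
C0021641	Insulin	insulin	Chemicals & Drugs
C0004057	Aspirin	aspirin	Chemicals & Drugs
C0700899	Concerta	concerta	Chemicals & Drugs
C1170050	Vyvanse	vyvanse	Chemicals & Drugs
C0721754	Strattera	strattera	Chemicals & Drugs
C0699129	Plavix	plavix	Chemicals & Drugs
C0875968	Diovan	diovan	Chemicals & Drugs
C0723277	Valium	valium	Chemicals & Drugs
C0002800	Immunologic factor	i|immunologic factor	Chemicals & Drugs
C0018787	Heart	heart	Anatomy
C0023216	Leg	leg	Anatomy
C0455873	Bad	bad	Chemicals & Drugs
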