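gene	drug	role	strength	evidence_auc_fold	evidence_clearance_pct
CYP2D6	paroxetine	inhibitor	strong	6.9	
CYP2D6	fluoxetine	inhibitor	strong	6	
CYP2D6	quinidine	inhibitor	strong		88
CYP2D6	duloxetine	inhibitor	moderate	2.6	
CYP2D6	cimetidine	inhibitor	weak	1.5	
CYP2D6	codeine	substrate	not_applicable		
CYP2D6	tramadol	substrate	not_applicable		
CYP2D6	metoprolol	substrate	not_applicable		
CYP2D6	atomoxetine	substrate	not_applicable		
CYP2D6	nortriptyline	substrate	not_applicable		
CYP2D6	risperidone	substrate	not_applicable		
CYP2C19	fluvoxamine	inhibitor	strong	6.2	
CYP2C19	fluconazole	inhibitor	moderate		62
CYP2C19	omeprazole	inhibitor	moderate	2.3	
CYP2C19	cimetidine	inhibitor	weak	1.4	
CYP2C19	rifampin	inducer	not_applicable		
CYP2C19	citalopram	substrate	not_applicable		
CYP2C19	omeprazole	substrate	not_applicable		
CYP2C19	clopidogrel	substrate	not_applicable		
CYP2C19	sertraline	substrate	not_applicable		
CYP2C19	voriconazole	substrate	not_applicable		
CYP2C9	fluconazole	inhibitor	moderate	2.8	
CYP2C9	amiodarone	inhibitor	moderate		55
CYP2C9	sulfamethoxazole	inhibitor	weak	1.6	
CYP2C9	rifampin	inducer	not_applicable		
CYP2C9	warfarin	substrate	not_applicable		
CYP2C9	phenytoin	substrate	not_applicable		
CYP2C9	celecoxib	substrate	not_applicable		
CYP2C9	ibuprofen	substrate	not_applicable		
CYP2B6	ticlopidine	inhibitor	strong	5.1	
CYP2B6	voriconazole	inhibitor	moderate		60
CYP2B6	clopidogrel	inhibitor	weak	1.8	
CYP2B6	rifampin	inducer	not_applicable		
CYP2B6	carbamazepine	inducer	not_applicable		
CYP2B6	efavirenz	substrate	not_applicable		
CYP3A5	ketoconazole	inhibitor	strong	7.5	
CYP3A5	erythromycin	inhibitor	moderate	3.5	
CYP3A5	fluvoxamine	inhibitor	weak	1.6	
CYP3A5	rifampin	inducer	not_applicable		
CYP3A5	carbamazepine	inducer	not_applicable		
CYP3A5	phenytoin	inducer	not_applicable		
CYP3A5	tacrolimus	substrate	not_applicable		
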