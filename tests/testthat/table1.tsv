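Gene	Drugs
CYP2B6	Efavirenz
CYP2C19	Amitriptyline, citalopram, clobazam, clomipramine, clopidogrel, doxepin, escitalopram, esomeprazole, imipramine, lansoprazole, omeprazole, pantoprazole, prasugrel, sertraline, ticagrelor, trimipramine, voriconazole
CYP2C9	Aspirin, celecoxib, flurbiprofen, ibuprofen, lornoxicam, meloxicam, naproxen, phenytoin, piroxicam, tenoxicam, warfarin
CYP2D6	Amiodarone, amitriptyline, amphetamine, aripiprazole, atenolol, atomoxetine, bisoprolol, brexpiprazole, cavedilol, clomipramine, clonidine, clozapine, codeine, desipramine, doxepin, duloxetine, eliglustat, flecainide, fluoxetine, fluphenazine, fluvoxamine, haloperidol, hydrocodone, iloperidone, imipramine, methylphenidate, metoprolol, mirtazapine, moclobemide, nebivolol, nortriptyline, odansetron, olanzapine, oxycodone, paroxetine, perphenazine, pimozide, propafenone, propranolol, quetiapine, risperidone, tamoxifen, tetrabenazine, tramadol, tropisetron, trimipramine, venlafaxine, vortioxetine, zuclopenthixol
CYP3A5	Tacrolimus
HLA-A	Carbamazepine (*31:01)
HLA-B	Abacavir (*57:01), allopurinol (*58:01), carbamazepine (*15:02), oxcarbazepine (*15:02), phenytoin (*15:02)
NUDT15	Azathioprine, mercaptopurine, thioguanine
SLCO1B1	Atorvastatin, fluvastatin, rosuvastatin, simvastatin
TPMT	Azathioprine, mercaptopurine, thioguanine
VKORC1	Acenocoumarol, warfarin
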