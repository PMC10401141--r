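pt,soc
Dizziness,Cardiac disorders
Dizziness,Nervous system disorders
Tachycardia,Cardiac disorders
Cardiorespiratory arrest,Cardiac disorders
Palpitations,Cardiac disorders
Syncope,Cardiac disorders
Syncope,Nervous system disorders
Sinus tachycardia,Cardiac disorders
Cardiac arrest,Cardiac disorders
Arrhythmia,Cardiac disorders
Bradycardia,Cardiac disorders
Myocarditis,Cardiac disorders
Atrial septal defect,Cardiac disorders
Atrial septal defect,"Congenital, familial and genetic disorders"
Cardiogenic shock,Cardiac disorders
Torsade de pointes,Cardiac disorders
Cardiomyopathy,Cardiac disorders
Dizziness postural,Cardiac disorders
Dizziness postural,Nervous system disorders
Ventricular extrasystoles,Cardiac disorders
Cyanosis,Cardiac disorders
Cardiovascular disorder,Cardiac disorders
Ventricular tachycardia,Cardiac disorders
Long QT syndrome,Cardiac disorders
Long QT syndrome,"Congenital, familial and genetic disorders"
Ventricular fibrillation,Cardiac disorders
Ventricular septal defect,Cardiac disorders
Ventricular septal defect,"Congenital, familial and genetic disorders"
Congestive cardiomyopathy,Cardiac disorders
Brugada syndrome,Cardiac disorders
Tricuspid valve incompetence,Cardiac disorders
Supraventricular tachycardia,Cardiac disorders
Patent ductus arteriosus,Cardiac disorders
Patent ductus arteriosus,"Congenital, familial and genetic disorders"
Ventricular arrhythmia,Cardiac disorders
Tachyarrhythmia,Cardiac disorders
Bundle branch block right,Cardiac disorders
Extrasystoles,Cardiac disorders
Nausea,Gastrointestinal disorders
Vomiting,Gastrointestinal disorders
Headache,Nervous system disorders
Insomnia,Psychiatric disorders
Rash,Skin and subcutaneous tissue disorders
Fatigue,General disorders and administration site conditions
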