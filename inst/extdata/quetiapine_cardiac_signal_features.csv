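pt,n,ror025,deaths,ime_dme,evidence,published_score,published_level
Dizziness,205,1.39,8,NA,++,4,weak
Tachycardia,138,4.82,3,IME,++,6,moderate
Cardiorespiratory arrest,57,4.64,57,IME,+,7,moderate
Palpitations,57,1.44,0,IME,++,5,moderate
Syncope,56,1.59,0,NA,++,4,weak
Sinus tachycardia,48,10.33,0,IME,++,6,moderate
Cardiac arrest,45,1.73,25,IME,+,5,moderate
Arrhythmia,37,2.12,11,IME,++,6,moderate
Bradycardia,35,1.57,6,IME,++,4,weak
Myocarditis,28,5.55,9,IME,++,7,moderate
Atrial septal defect,19,5.7,0,NA,-,3,weak
Cardiogenic shock,16,2.51,1,NA,-,2,weak
Torsade de pointes,13,3.77,0,DME,++,6,moderate
Cardiomyopathy,13,2.13,1,IME,++,5,moderate
Dizziness postural,11,2.36,0,NA,++,4,weak
Ventricular extrasystoles,11,2.77,0,NA,-,2,weak
Cyanosis,11,1.74,0,NA,-,1,weak
Cardiovascular disorder,9,1.32,3,NA,++,3,weak
Ventricular tachycardia,9,1.25,1,IME,++,3,weak
Long QT syndrome,8,4.47,0,NA,++,3,weak
Ventricular fibrillation,8,1.64,0,DME,-,2,weak
Ventricular septal defect,8,2.77,0,NA,-,1,weak
Congestive cardiomyopathy,7,2.48,0,IME,++,4,weak
Brugada syndrome,7,11.82,0,NA,-,2,weak
Tricuspid valve incompetence,7,2.18,0,NA,-,1,weak
Supraventricular tachycardia,6,1.19,0,IME,++,3,weak
Patent ductus arteriosus,6,2.85,0,NA,-,1,weak
Ventricular arrhythmia,5,1.7,2,IME,++,4,weak
Tachyarrhythmia,5,2.97,0,IME,++,4,weak
Bundle branch block right,5,2.12,0,NA,-,1,weak
Extrasystoles,5,1.24,0,NA,-,0,weak
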