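atrial fibrillation
sinus rhythm
sinus bradycardia
sinus tachycardia
left bundle branch block
right bundle branch block
first degree AV block
premature ventricular complex
premature atrial complex
ST elevation
ST depression
T wave inversion
QT prolongation
left ventricular hypertrophy
right axis deviation
left axis deviation
myocardial infarction
anterior infarct
inferior infarct
ischemia
pacemaker rhythm
ventricular tachycardia
supraventricular tachycardia
atrial flutter
low voltage
poor R wave progression
nonspecific changes
borderline ECG
abnormal ECG
normal ECG
compare with prior
follow up
cardiology consult
digoxin effect
hyperkalemia
biphasic T wave
U wave present
early repolarization
junctional rhythm
bigeminy
trigeminy
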