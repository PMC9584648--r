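Case,Age,Sex,Etiology,State,Diagnose,Auditory,Visual,Motor,Oromotor,Communication,Arousal,Total
1,38,F,ICH,Acute,UWS,1,0,2,0,0,2,5
2,75,F,Stroke,Acute,UWS,1,1,2,0,0,1,5
3,28,F,Anoxic,Chronic,UWS,1,0,1,2,0,2,6
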