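furious	anger	1
rage	anger	1
irate	anger	1
afraid	fear	1
terrified	fear	1
panic	fear	1
reliable	trust	1
faithful	trust	1
dependable	trust	1
revolting	disgust	1
nauseating	disgust	1
repulsive	disgust	1
eager	anticipation	1
expectant	anticipation	1
awaiting	anticipation	1
astonished	surprise	1
startled	surprise	1
stunned	surprise	1
joyful	joy	1
delighted	joy	1
cheerful	joy	1
mournful	sadness	1
gloomy	sadness	1
sorrowful	sadness	1
terrified	sadness	1
awaiting	trust	1
furious	disgust	1
wonderful	joy	0
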