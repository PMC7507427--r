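>MyoD synthetic consensus-derived E-box (CAGCTG)
A [  1 97  1  1  1  1 ]
C [ 97  1  1 97  1  1 ]
G [  1  1 97  1  1 97 ]
T [  1  1  1  1 97  1 ]
>MyoG synthetic consensus-derived E-box (AACAGCTG)
A [ 97 97  1 97  1  1  1  1 ]
C [  1  1 97  1  1 97  1  1 ]
G [  1  1  1  1 97  1  1 97 ]
T [  1  1  1  1  1  1 97  1 ]
>CTCF synthetic consensus-derived (CCGCGAGGTGGCAG)
A [  1  1  1  1  1 97  1  1  1  1  1  1 97  1 ]
C [ 97 97  1 97  1  1  1  1  1  1  1 97  1  1 ]
G [  1  1 97  1 97  1 97 97  1 97 97  1  1 97 ]
T [  1  1  1  1  1  1  1  1 97  1  1  1  1  1 ]
>Runx synthetic consensus-derived (TGTGGTTT)
A [  1  1  1  1  1  1  1  1 ]
C [  1  1  1  1  1  1  1  1 ]
G [  1 97  1 97 97  1  1  1 ]
T [ 97  1 97  1  1 97 97 97 ]
>AP-1 synthetic consensus-derived (TGACTCA)
A [  1  1 97  1  1  1 97 ]
C [  1  1  1 97  1 97  1 ]
G [  1 97  1  1  1  1  1 ]
T [ 97  1  1  1 97  1  1 ]
>ATF3 synthetic consensus-derived (TGACGTCA)
A [  1  1 97  1  1  1  1 97 ]
C [  1  1  1 97  1  1 97  1 ]
G [  1 97  1  1 97  1  1  1 ]
T [ 97  1  1  1  1 97  1  1 ]
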