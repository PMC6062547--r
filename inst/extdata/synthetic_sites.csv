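protein_id,position,label
SYNPROT001,12,positive
SYNPROT001,42,negative
SYNPROT001,67,negative
SYNPROT002,18,positive
SYNPROT002,46,negative
SYNPROT002,75,negative
SYNPROT003,12,positive
SYNPROT003,42,negative
SYNPROT003,75,negative
SYNPROT004,13,positive
SYNPROT004,43,negative
SYNPROT004,74,negative
SYNPROT005,22,positive
SYNPROT005,50,negative
SYNPROT005,72,negative
SYNPROT006,20,positive
SYNPROT006,54,negative
SYNPROT006,90,negative
SYNPROT007,21,positive
SYNPROT007,57,negative
SYNPROT007,81,negative
SYNPROT008,16,positive
SYNPROT008,51,negative
SYNPROT008,73,negative
SYNPROT009,12,positive
SYNPROT009,40,negative
SYNPROT009,70,negative
SYNPROT010,15,positive
SYNPROT010,39,negative
SYNPROT010,65,negative
SYNPROT011,23,positive
SYNPROT011,50,negative
SYNPROT011,73,negative
SYNPROT012,19,positive
SYNPROT012,44,negative
SYNPROT012,73,negative
SYNPROT013,19,positive
SYNPROT013,48,negative
SYNPROT013,70,negative
SYNPROT014,14,positive
SYNPROT014,41,negative
SYNPROT014,67,negative
SYNPROT015,12,positive
SYNPROT015,48,negative
SYNPROT015,81,negative
SYNPROT016,17,positive
SYNPROT016,44,negative
SYNPROT016,68,negative
SYNPROT017,18,positive
SYNPROT017,47,negative
SYNPROT017,76,negative
SYNPROT018,15,positive
SYNPROT018,38,negative
SYNPROT018,64,negative
SYNPROT019,15,positive
SYNPROT019,47,negative
SYNPROT019,77,negative
SYNPROT020,20,positive
SYNPROT020,48,negative
SYNPROT020,79,negative
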