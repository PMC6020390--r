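# Octave-band constants for the unaided Speech Intelligibility Index.
# importance: standard octave-band importance function (sums to 1).
# band_speech_level: long-term average speech level per octave band for
#   average vocal effort, expressed in dB HL.
# Audibility window: speech peaks sit peak_offset dB above the band level
# and audibility falls linearly over dynamic_range dB.
bands: [250, 500, 1000, 2000, 4000, 8000]
importance: [0.0617, 0.1671, 0.2373, 0.2648, 0.2142, 0.0549]
band_speech_level: [45, 50, 45, 38, 33, 28]
dynamic_range: 30
peak_offset: 15
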