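# Nine disjoint place-of-articulation categories covering the ARPAbet-style
# phone labels used by the stimulus fixture (silence /sp/ excluded). Vowels
# are kept as a single category; consonants follow the standard articulatory
# places.
bilabial: [p, b, m, w]
labiodental: [f, v]
dental: [th, dh]
alveolar: [t, d, s, z, "n", l, r]
postalveolar: [sh, zh, ch, jh]
palatal: ["y"]
velar: [k, g, ng]
glottal: [hh]
vowel: [aa, ae, ah, ao, aw, ay, eh, er, ey, ih, iy, ow, oy, uh, uw]
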