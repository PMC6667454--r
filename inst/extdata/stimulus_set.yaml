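# Question-and-answer stimulus set used by the decoding task.
# Four QA sets; the answers in a set are the valid responses to each of the
# set's questions. Phone sequences are fixed ARPAbet-style transcriptions
# (stress omitted) so that synthetic sessions and HMM construction are
# reproducible without a forced aligner. /sp/ boundary silences are added by
# the models, not listed here.
qa_sets:
  - set: 1
    questions:
      - "Which musical instrument do you like listening to?"
      - "Which musical instrument do you dislike hearing?"
    answers:
      - "Piano"
      - "Violin"
      - "Electric guitar"
      - "Drums"
      - "Synthesizer"
      - "None of these"
  - set: 2
    questions:
      - "How is your room currently?"
    answers:
      - "Bright"
      - "Dark"
      - "Hot"
      - "Cold"
      - "Fine"
  - set: 3
    questions:
      - "From 0 to 10, how much pain are you in?"
      - "From 0 to 10, how nauseous are you?"
      - "From 0 to 10, how happy do you feel?"
      - "From 0 to 10, how stressed are you?"
      - "From 0 to 10, how comfortable are you?"
    answers:
      - "Zero"
      - "One"
      - "Two"
      - "Three"
      - "Four"
      - "Five"
      - "Six"
      - "Seven"
      - "Eight"
      - "Nine"
      - "Ten"
  - set: 4
    questions:
      - "When do you want me to check back on you?"
    answers:
      - "Today"
      - "Tomorrow"
phone_seqs:
  "Which musical instrument do you like listening to?":
    [w, ih, ch, m, "y", uw, z, ih, k, ah, l, ih, "n", s, t, r, ah, m, ah, "n", t,
     d, uw, "y", uw, l, ay, k, l, ih, s, ah, "n", ih, ng, t, uw]
  "Which musical instrument do you dislike hearing?":
    [w, ih, ch, m, "y", uw, z, ih, k, ah, l, ih, "n", s, t, r, ah, m, ah, "n", t,
     d, uw, "y", uw, d, ih, s, l, ay, k, hh, ih, r, ih, ng]
  "How is your room currently?":
    [hh, aw, ih, z, "y", ao, r, r, uw, m, k, er, ah, "n", t, l, iy]
  "From 0 to 10, how much pain are you in?":
    [f, r, ah, m, z, ih, r, ow, t, uw, t, eh, "n", hh, aw, m, ah, ch, p, ey, "n",
     aa, r, "y", uw, ih, "n"]
  "From 0 to 10, how nauseous are you?":
    [f, r, ah, m, z, ih, r, ow, t, uw, t, eh, "n", hh, aw, "n", ao, sh, ah, s,
     aa, r, "y", uw]
  "From 0 to 10, how happy do you feel?":
    [f, r, ah, m, z, ih, r, ow, t, uw, t, eh, "n", hh, aw, hh, ae, p, iy,
     d, uw, "y", uw, f, iy, l]
  "From 0 to 10, how stressed are you?":
    [f, r, ah, m, z, ih, r, ow, t, uw, t, eh, "n", hh, aw, s, t, r, eh, s, t,
     aa, r, "y", uw]
  "From 0 to 10, how comfortable are you?":
    [f, r, ah, m, z, ih, r, ow, t, uw, t, eh, "n", hh, aw, k, ah, m, f, er, t,
     ah, b, ah, l, aa, r, "y", uw]
  "When do you want me to check back on you?":
    [w, eh, "n", d, uw, "y", uw, w, aa, "n", t, m, iy, t, uw, ch, eh, k, b, ae, k,
     aa, "n", "y", uw]
  "Piano": [p, iy, ae, "n", ow]
  "Violin": [v, ay, ah, l, ih, "n"]
  "Electric guitar": [ih, l, eh, k, t, r, ih, k, g, ih, t, aa, r]
  "Drums": [d, r, ah, m, z]
  "Synthesizer": [s, ih, "n", th, ah, s, ay, z, er]
  "None of these": ["n", ah, "n", ah, v, dh, iy, z]
  "Bright": [b, r, ay, t]
  "Dark": [d, aa, r, k]
  "Hot": [hh, aa, t]
  "Cold": [k, ow, l, d]
  "Fine": [f, ay, "n"]
  "Zero": [z, ih, r, ow]
  "One": [w, ah, "n"]
  "Two": [t, uw]
  "Three": [th, r, iy]
  "Four": [f, ao, r]
  "Five": [f, ay, v]
  "Six": [s, ih, k, s]
  "Seven": [s, eh, v, ah, "n"]
  "Eight": [ey, t]
  "Nine": ["n", ay, "n"]
  "Ten": [t, eh, "n"]
  "Today": [t, ah, d, ey]
  "Tomorrow": [t, ah, m, aa, r, ow]
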