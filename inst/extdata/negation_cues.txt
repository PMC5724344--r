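# Negation cue lexicon: one lowercase cue token per line.
# The scope rule removes the cue and everything after it to the
# sentence end. "ei" is the Finnish negation verb, kept as a
# localization placeholder.
no
not
without
ei
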