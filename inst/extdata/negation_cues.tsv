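# Negation and hedge cues: surface<TAB>{negation|hedge}
# Negation cues scope over the noun group they open (or immediately
# precede); hedge cues mark non-exclusions, which the scheme records as
# negative because only clearly positive findings may support a label.
no	negation
not	negation
without	negation
absence of	negation
free of	negation
negative for	negation
cannot be completely excluded	hedge
cannot be entirely excluded	hedge
cannot be confidently excluded	hedge
cannot be excluded	hedge
can not be excluded	hedge
cannot exclude	hedge
can not exclude	hedge
is not excluded	hedge
not excluded	hedge
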