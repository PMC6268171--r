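# Ionization rule table, version 1.
#
# Group pattern -> literature pKa. A group is toggled (both protonation
# states emitted) when its pKa falls inside the physiological window
# [ph_low - 2, ph_high + 2]; acids with pKa below the window additionally
# emit their dominant deprotonated form, bases whose conjugate acid lies
# above the window their dominant protonated form. Recognizers are named
# graph patterns interpreted by the enumerator.
version: 1
groups:
  carboxylic_acid:  {recognizer: carboxylic_acid,  pka: 4.76, kind: acid}
  phosphate_oh:     {recognizer: phosphate_oh,     pka: 7.21, kind: acid}
  tetrazole_nh:     {recognizer: tetrazole_nh,     pka: 4.90, kind: acid}
  phenol:           {recognizer: phenol,           pka: 9.95, kind: acid}
  sulfonic_acid:    {recognizer: sulfonic_acid,    pka: -1.0, kind: acid}
  aliphatic_amine:  {recognizer: aliphatic_amine,  pka: 10.64, kind: base}
  imidazole_base:   {recognizer: imidazole_base,   pka: 6.95, kind: base}
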