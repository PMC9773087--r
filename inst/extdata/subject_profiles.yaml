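# Mean skin colorimetry (CIELAB, D65/10 degrees) and whiteness coefficient
# of the two study faces: OM (Chinese male), OF (Chinese female).
OM:
  L_sub: 63.74
  C_sub: 21.38
  beta: 76.0
OF:
  L_sub: 66.83
  C_sub: 17.99
  beta: 76.0
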