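# Bjellqvist-style pKa values for ionizable groups (pH units).
# Override with loadPkaTable(path) to use a different table.
nterm: 7.50
cterm: 3.55
# keys quoted: bare Y/N would parse as YAML booleans
sidechain:
  "D": 4.05
  "E": 4.45
  "C": 9.00
  "Y": 10.00
  "H": 5.98
  "K": 10.00
  "R": 12.00
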