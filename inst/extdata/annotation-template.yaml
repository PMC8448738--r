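# Subunit annotation template for a hemidiscoidal cyanobacterial PBS.
#
# This is a *template*, not a derived mapping: deposited entries do not
# encode which chain sits in which core cylinder/layer or rod, so the
# chain ids below must be confirmed against the deposition being analysed
# (auto_annotate() can propose draft roles from chain heuristics).
#
# Vocabulary:
#   roles:        ApcA ApcB ApcC ApcD ApcE ApcF CpcA CpcB CpcC CpcG other
#   compartment:  core | rod
#   cylinder:     A A' B C C'        (core only; layers 1-4 per cylinder)
#   rod_name:     R1 R1' R2 R2' R3 R3' Rb Rb' Rs1 Rs1' Rs2 Rs2' Rt Rt'
#
# Example entries (replace chain ids with the deposition's):
chains:
  A:
    role: ApcD
    compartment: core
    cylinder: A
    layer: 4
  B:
    role: ApcB
    compartment: core
    cylinder: A
    layer: 4
  C:
    role: ApcE
    compartment: core
    cylinder: A
    layer: 3
  D:
    role: ApcF
    compartment: core
    cylinder: A
    layer: 3
patterns: []
# patterns take a `match` regular expression on chain ids, e.g.
# - match: "^R1"
#   role: CpcA
#   compartment: rod
#   rod_name: R1
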