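# Balanced stoichiometries of the packaged reaction set.
# Species compositions live in table1_species.tsv.
- label: EEq4a
  reactants:
    "1": 1
    "Cu(H2O)5^2+": 1
  products:
    "2a(H2O)2": 1
    "H2O": 3
    "H+": 1
  electrons: 0
- label: EEq4b
  reactants:
    "1": 1
    "Cu(H2O)5^2+": 1
  products:
    "2b(H2O)2": 1
    "H2O": 3
    "H+": 1
  electrons: 0
- label: EEq4c
  reactants:
    "1": 1
    "Cu(H2O)5^2+": 1
  products:
    "2c(H2O)2": 1
    "H2O": 3
    "H+": 1
  electrons: 0
- label: EEq5
  reactants:
    "3": 1
    "Cu(H2O)5^2+": 1
  products:
    "4(H2O)": 1
    "H2O": 4
    "H+": 1
  electrons: 0
- label: EEq6a
  reactants:
    "Im": 1
    "Cu(H2O)5^2+": 1
  products:
    "Cu(Im)(H2O)4^2+": 1
    "H2O": 1
  electrons: 0
- label: EEq6b
  reactants:
    "Im": 2
    "Cu(H2O)5^2+": 1
  products:
    "Cu(Im)2(H2O)3^2+": 1
    "H2O": 2
  electrons: 0
- label: EEq7a
  reactants:
    "2a(H2O)2": 1
    "Im": 1
  products:
    "2a(Im)(H2O)": 1
    "H2O": 1
  electrons: 0
- label: EEq7b
  reactants:
    "1": 1
    "Cu(Im)(H2O)4^2+": 1
  products:
    "2a(Im)(H2O)": 1
    "H2O": 3
    "H+": 1
  electrons: 0
- label: EEq8a
  reactants:
    "2a(Im)(H2O)": 1
    "Im": 1
  products:
    "2a(Im)2": 1
    "H2O": 1
  electrons: 0
- label: EEq8b
  reactants:
    "1": 1
    "Cu(Im)2(H2O)3^2+": 1
  products:
    "2a(Im)2": 1
    "H2O": 3
    "H+": 1
  electrons: 0
- label: EEq9a
  reactants:
    "4(H2O)": 1
    "Im": 1
  products:
    "4(Im)": 1
    "H2O": 1
  electrons: 0
- label: EEq9b
  reactants:
    "3": 1
    "Cu(H2O)5^2+": 1
    "Im": 1
  products:
    "4(Im)": 1
    "H2O": 5
    "H+": 1
  electrons: 0
- label: EEq10
  reactants:
    "4(Im)": 1
    "Im": 1
  products:
    "4(Im)2": 1
  electrons: 0
- label: EEq11
  reactants:
    "4(Im)": 1
    "Im": 1
    "1": 1
  products:
    "2a(Im)2": 1
    "3": 1
  electrons: 0
- label: EEq12
  reactants:
    "5": 1
    "Cu(H2O)5^2+": 1
  products:
    "6(H2O)2": 1
    "H2O": 3
  electrons: 0
- label: EEq13
  reactants:
    "6(H2O)2": 1
    "Im": 1
  products:
    "6(Im)(H2O)": 1
    "H2O": 1
  electrons: 0
- label: EEq14
  reactants:
    "6(Im)(H2O)": 1
    "NMA": 1
  products:
    "7": 1
    "H2O": 1
  electrons: 0
- label: EEq15a
  reactants:
    "1": 1
    "6(H2O)2": 1
  products:
    "8a": 1
    "H2O": 2
    "H+": 1
  electrons: 0
- label: EEq15b
  reactants:
    "2a(H2O)2": 1
    "5": 1
  products:
    "8a": 1
    "H2O": 2
  electrons: 0
- label: EEq16a
  reactants:
    "1": 1
    "6(Im)(H2O)": 1
  products:
    "9": 1
    "H2O": 1
    "H+": 1
  electrons: 0
- label: EEq16b
  reactants:
    "9": 1
  products:
    "8a": 1
    "Im": 1
  electrons: 0
- label: EEq16c
  reactants:
    "9": 1
    "H2O": 1
  products:
    "5": 1
    "2a(Im)(H2O)": 1
  electrons: 0
- label: EEq17
  reactants:
    "1": 1
    "Cu(H2O)3^+": 1
  products:
    "2I(H2O)": 1
    "H2O": 2
    "H+": 1
  electrons: 0
- label: EEq18
  reactants:
    "Im": 1
    "Cu(H2O)3^+": 1
  products:
    "Cu(Im)(H2O)+": 1
    "H2O": 2
  electrons: 0
- label: EEq19a
  reactants:
    "Im": 1
    "Cu(Im)(H2O)+": 1
  products:
    "Cu(Im)2+": 1
    "H2O": 1
  electrons: 0
- label: EEq19b
  reactants:
    "5": 1
    "Cu(Im)(H2O)+": 1
  products:
    "Cu(Im)(H13H14)+": 1
    "H2O": 1
  electrons: 0
- label: EEq19c
  reactants:
    "5": 1
    "Cu(Im)(H2O)+": 1
  products:
    "Cu(Im)(H14H13)+": 1
    "H2O": 1
  electrons: 0
- label: EEq20
  reactants:
    "1": 1
    "Cu(Im)(H2O)+": 1
  products:
    "2I(Im)": 1
    "H2O": 1
    "H+": 1
  electrons: 0
- label: EEq21
  reactants:
    "2I(Im)": 1
    "Im": 1
  products:
    "2I(Im)2": 1
  electrons: 0
- label: EEq22
  reactants:
    "1": 1
    "Cu(Im)2+": 1
  products:
    "2I(Im)2": 1
    "H+": 1
  electrons: 0
- label: EEq23
  reactants:
    "5": 1
    "Cu(H2O)3^+": 1
  products:
    "6I": 1
    "H2O": 3
  electrons: 0
- label: EEq24a
  reactants:
    "1": 1
    "6I": 1
  products:
    "8aI": 1
    "H+": 1
  electrons: 0
- label: EEq24b
  reactants:
    "1": 1
    "6I": 1
  products:
    "8bI": 1
    "H+": 1
  electrons: 0
- label: EEq25
  reactants:
    "NMA": 1
    "6I": 1
  products:
    "7I": 1
  electrons: 0
- label: EEq26
  reactants:
    "Im": 1
    "6I": 1
  products:
    "6I(Im)": 1
  electrons: 0
- label: EEq27
  reactants:
    "2a(H2O)2": 1
  products:
    "2aI(H2O)": 1
    "H2O": 1
  electrons: 1
- label: EEq28
  reactants:
    "2a(Im)(H2O)": 1
  products:
    "2I(Im)": 1
    "H2O": 1
  electrons: 1
- label: EEq29a
  reactants:
    "2a(Im)2": 1
    "5": 1
    "H+": 1
  products:
    "1": 1
    "Cu(Im)(H13H14)+": 1
    "Im": 1
  electrons: 1
- label: EEq29b
  reactants:
    "2a(Im)2": 1
    "5": 1
    "H+": 1
  products:
    "1": 1
    "Cu(Im)(H14H13)+": 1
    "Im": 1
  electrons: 1
- label: EEq30
  reactants:
    "2a(Im)2": 1
    "5": 1
    "H+": 1
  products:
    "1": 1
    "6I(Im)": 1
    "Im": 1
  electrons: 1
- label: EEq31
  reactants:
    "2a(Im)2": 1
    "5": 1
    "H+": 1
  products:
    "1": 1
    "6I": 1
    "Im": 2
  electrons: 1
- label: EEq32
  reactants:
    "6(H2O)2": 1
  products:
    "6I": 1
    "H2O": 2
  electrons: 1
- label: EEq33
  reactants:
    "6(Im)(H2O)": 1
  products:
    "6I": 1
    "Im": 1
    "H2O": 1
  electrons: 1
- label: EEq34
  reactants:
    "7": 1
  products:
    "6I": 1
    "Im": 1
    "NMA": 1
  electrons: 1
- label: EEq35
  reactants:
    "6(Im)(H2O)": 1
  products:
    "6I(Im)": 1
    "H2O": 1
  electrons: 1
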