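{
  "_comment": "Thermodynamic formation constants, log10 at 25 C and infinite dilution. Reactions are written with the free ligand actually used by the solver (OH-, HCO3-, CO3 2-, SO4 2-). Values are rounded critical-compilation numbers (NIST 46 / Smith & Martell; MINTEQ-type databases); edit and pass to default_constants(file=...) to override.",
  "logK_H_CO2": {"value": -1.47, "reaction": "CO2(g) = CO2(aq), mol/L/atm Henry constant", "source": "Plummer & Busenberg 1982"},
  "logKa1": {"value": -6.35, "reaction": "CO2(aq) + H2O = H+ + HCO3-", "source": "Plummer & Busenberg 1982"},
  "logKa2": {"value": -10.33, "reaction": "HCO3- = H+ + CO3 2-", "source": "Plummer & Busenberg 1982"},
  "logKw": {"value": -14.0, "reaction": "H2O = H+ + OH-", "source": "standard, 25 C"},
  "logK_CuOH": {"value": 6.3, "reaction": "Cu2+ + OH- = CuOH+", "source": "NIST 46"},
  "logK_CuCO3": {"value": 6.75, "reaction": "Cu2+ + CO3 2- = CuCO3(aq)", "source": "NIST 46"},
  "logK_CuHCO3": {"value": 2.7, "reaction": "Cu2+ + HCO3- = CuHCO3+", "source": "MINTEQ-type compilation; literature values for this species diverge (1.8-2.7)"},
  "logK_CoOH": {"value": 4.3, "reaction": "Co2+ + OH- = CoOH+", "source": "NIST 46"},
  "logK_CoHCO3": {"value": 1.9, "reaction": "Co2+ + HCO3- = CoHCO3+", "source": "MINTEQ-type compilation"},
  "logK_MgSO4": {"value": 2.37, "reaction": "Mg2+ + SO4 2- = MgSO4(aq)", "source": "NIST 46"},
  "logK_CaSO4": {"value": 2.3, "reaction": "Ca2+ + SO4 2- = CaSO4(aq)", "source": "NIST 46"}
}
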