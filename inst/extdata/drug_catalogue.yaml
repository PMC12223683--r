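# Drug catalogue: per-kg dose limits and default solution concentrations.
#
# The dose limits below are documented literature defaults for adult
# single-shot peripheral/regional use, NOT values taken from any single
# study; review and edit them before applying the calculator to a new
# clinical context.  Concentrations are common commercial preparations
# (mg per mL) used when a vignette asks for a volume.
drugs:
  lidocaine:
    dose_limit: 4.5      # mg/kg
    concentration: 10    # mg/mL (1% solution)
  levobupivacaine:
    dose_limit: 2
    concentration: 2.5   # 0.25% solution
  ropivacaine:
    dose_limit: 3
    concentration: 7.5   # 0.75% solution
# Major CYP1A2 / CYP3A inhibitors recognised as a metabolic risk factor.
# Membership is a plain lookup; no interaction inference is performed.
inhibitors:
  - ciprofloxacin
  - clarithromycin
  - erythromycin
  - azithromycin
  - fluvoxamine
  - ketoconazole
  - itraconazole
  - voriconazole
  - ritonavir
  - diltiazem
  - verapamil
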