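# tilsim default rule parameters (schema v1).
# Probabilities are per agent step (dtHours), speeds um/min, times hours.
# Calibrated so the baseline neoantigen profile (kA = 20, kI = 0.1) shows
# T-cell arrival around day 10, slowdown of tumour growth under immune
# attack and emergence of a PDL1+ population.
schema: tilsim-params
schema_version: 1
pKillNeg: 0.2
pKillPos: 0.09
pPdl1Induction: 0.1
inductionOnContact: false
pSupp: 0.12
il2DivisionThreshold: 0.015
tCellSpeed: 1.0
cancerSpeed: 0.05
cancerCycleTime: 36.0
tCellCycleTime: 12.0
tCellLifespan: 168.0
deadClearanceTime: 24.0
pNecrosis: 0.1
kA: 20.0
kI: 0.1
rBase: 0.31
lambdaVasc: 0.01
baseDensity: 0.05
maxTCellDivisions: 4
diffusionCoeff: 0.18
decayRate: 0.6931472
secretionRate: 1.0
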