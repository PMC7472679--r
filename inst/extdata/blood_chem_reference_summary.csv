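# Published two-decimal summary of the cohort 1-2 blood chemistries
# (baseline / round 1 / pooled rounds >= 2), used by chemistry_report()
# to flag cells whose recomputation from the per-animal panel disagrees.
group,n,analyte,mean,sd
baseline,24,pH,7.46,0.07
baseline,24,iCa,1.28,0.09
round1,20,pH,7.33,0.11
round1,20,iCa,1.23,0.08
other,43,pH,7.34,0.08
other,43,iCa,1.19,0.12
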