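# Blood-gas panels (pH, ionized calcium) from three cohorts of a swine hypoxic
# pseudo-PEA preparation, hand-transcribed from the study record. One row per
# animal-round that the animal survived to; status='missing' marks rounds whose
# chemistry was drawn but lost/not recorded; absent rows mean the animal did not
# survive to that round. bolus_ca / epi are per-round injection counts (cohort 3
# only; cohorts 1-2 received no calcium). suspect=TRUE flags cells whose printed
# source was ambiguous or physiologically implausible; they are transcribed
# verbatim and retained in computations but should not be over-interpreted.
cohort,animal,round,pH,iCa,bolus_ca,epi,status,suspect
1,1,baseline,7.46,1.29,,,ok,FALSE
1,1,1,7.29,1.21,,,ok,FALSE
1,1,2,7.32,1.12,,,ok,FALSE
1,1,3,7.31,1.1,,,ok,FALSE
1,1,4,7.28,1.17,,,ok,FALSE
1,1,5,7.29,1.2,,,ok,FALSE
1,2,baseline,7.5,1.26,,,ok,FALSE
1,2,1,7.27,1.21,,,ok,FALSE
1,2,2,7.23,1.24,,,ok,FALSE
1,2,3,7.37,1.23,,,ok,FALSE
1,2,4,7.34,1.28,,,ok,FALSE
1,2,5,7.35,1.26,,,ok,FALSE
1,3,baseline,7.47,1.28,,,ok,FALSE
1,3,1,7.32,1.24,,,ok,FALSE
1,3,2,7.32,1.25,,,ok,FALSE
1,3,3,7.29,1.24,,,ok,FALSE
1,3,4,7.32,1.27,,,ok,FALSE
1,3,5,7.4,1.25,,,ok,FALSE
1,4,baseline,7.49,1.29,,,ok,FALSE
1,4,1,7.25,1.2,,,ok,FALSE
1,4,2,7.2,1.25,,,ok,FALSE
1,4,3,7.24,1.18,,,ok,FALSE
1,4,4,7.29,1.15,,,ok,FALSE
1,4,5,7.24,1.17,,,ok,FALSE
1,5,baseline,7.5,1.35,,,ok,FALSE
1,5,1,7.53,1.33,,,ok,FALSE
1,5,2,7.48,1.26,,,ok,FALSE
1,5,3,7.51,1.26,,,ok,FALSE
1,5,4,7.49,1.25,,,ok,FALSE
1,5,5,7.31,1.25,,,ok,FALSE
1,6,baseline,7.49,1.36,,,ok,FALSE
1,6,1,7.46,1.25,,,ok,FALSE
1,6,2,7.46,1.22,,,ok,FALSE
1,6,3,7.39,1.25,,,ok,FALSE
1,6,4,7.36,1.28,,,ok,FALSE
1,6,5,7.42,1.72,,,ok,TRUE
1,7,baseline,7.48,1.39,,,ok,FALSE
1,7,1,7.51,1.34,,,ok,FALSE
1,7,2,7.48,1.33,,,ok,FALSE
1,7,3,7.51,1.3,,,ok,FALSE
1,7,4,7.5,1.28,,,ok,FALSE
1,7,5,7.5,1.28,,,ok,FALSE
1,8,baseline,7.51,1.41,,,ok,FALSE
1,8,1,7.33,1.29,,,ok,FALSE
1,9,baseline,7.5,1.4,,,ok,FALSE
1,9,1,7.4,1.07,,,ok,FALSE
1,9,2,7.44,1.27,,,ok,FALSE
1,9,3,7.45,1.28,,,ok,FALSE
1,9,4,7.38,1.28,,,ok,FALSE
1,10,baseline,7.47,1.36,,,ok,FALSE
1,10,1,7.09,1.28,,,ok,FALSE
1,11,baseline,7.48,1.33,,,ok,FALSE
1,11,1,7.24,1.32,,,ok,FALSE
1,11,2,7.27,1.25,,,ok,FALSE
1,12,baseline,7.5,1.17,,,ok,FALSE
1,12,1,7.33,1.27,,,ok,FALSE
1,12,2,7.33,1.27,,,ok,FALSE
1,13,baseline,7.48,1.29,,,ok,FALSE
1,13,1,7.33,1.25,,,ok,FALSE
1,13,2,7.38,1.22,,,ok,FALSE
1,14,baseline,7.48,1.3,,,ok,FALSE
1,14,1,7.33,1.32,,,ok,FALSE
2,1,baseline,7.24,1.19,,,ok,TRUE
2,2,baseline,7.23,1.2,,,ok,TRUE
2,3,baseline,7.49,1.23,,,ok,FALSE
2,3,1,7.32,1.14,,,ok,FALSE
2,4,baseline,7.48,1.29,,,ok,FALSE
2,4,1,7.48,1.29,,,ok,FALSE
2,5,baseline,7.51,1.13,,,ok,FALSE
2,6,baseline,7.43,1.17,,,ok,FALSE
2,7,baseline,7.45,1.33,,,ok,FALSE
2,7,1,7.25,1.21,,,ok,FALSE
2,7,2,7.33,1.11,,,ok,FALSE
2,7,3,7.31,1.16,,,ok,FALSE
2,8,baseline,7.42,1.07,,,ok,FALSE
2,8,1,7.23,1.07,,,ok,FALSE
2,8,2,7.28,0.92,,,ok,FALSE
2,8,3,7.28,0.88,,,ok,FALSE
2,9,baseline,7.48,1.34,,,ok,FALSE
2,9,1,7.34,1.17,,,ok,FALSE
2,9,2,7.33,1.11,,,ok,FALSE
2,9,3,7.32,1.11,,,ok,FALSE
2,9,4,7.34,1.08,,,ok,FALSE
2,10,baseline,7.45,1.23,,,ok,FALSE
2,10,1,7.32,1.11,,,ok,FALSE
2,10,2,7.2,0.92,,,ok,FALSE
2,10,3,7.2,1.06,,,ok,FALSE
3,1,baseline,,,,,missing,FALSE
3,1,1,,,0,1,missing,FALSE
3,1,2,,,0,0,missing,FALSE
3,2,baseline,7.49,1.08,,,ok,FALSE
3,2,1,7.16,1.21,0,1,ok,FALSE
3,2,2,7.5,0.94,0,0,ok,FALSE
3,2,3,7.37,0.92,0,0,ok,FALSE
3,2,4,7.22,1.05,0,0,ok,FALSE
3,3,baseline,7.45,1.38,,,ok,FALSE
3,3,1,7.47,1.38,0,6,ok,FALSE
3,3,2,7.04,1.37,,,ok,TRUE
3,4,baseline,7.62,1.39,,,ok,TRUE
3,4,1,,,0,0,missing,TRUE
3,4,2,7.16,1.29,1,0,ok,TRUE
3,4,3,7.39,1.12,0,1,ok,TRUE
3,4,4,7.3,1.17,0,1,ok,TRUE
3,5,baseline,7.44,1.34,,,ok,FALSE
3,5,1,7.01,1.26,1,0,ok,FALSE
3,5,2,7.28,1.42,1,0,ok,FALSE
3,5,3,7.4,1.25,1,0,ok,FALSE
3,5,4,7.21,1.22,0,0,ok,FALSE
3,6,baseline,7.47,1.44,,,ok,FALSE
3,6,1,7.2,1.25,0,0,ok,FALSE
3,6,2,7.32,1.29,1,0,ok,FALSE
3,6,3,7.24,1.49,2,0,ok,FALSE
3,6,4,,,0,0,missing,FALSE
3,7,baseline,7.45,1.38,,,ok,FALSE
3,7,1,7.03,,0,0,missing,TRUE
3,7,2,,,5,8,missing,TRUE
3,8,baseline,7.47,1.4,,,ok,FALSE
3,8,1,7.44,1.3,3,0,ok,FALSE
3,8,2,7.4,1.24,3,0,ok,FALSE
3,8,3,7.34,1.36,2,0,ok,FALSE
3,8,4,,,1,2,missing,FALSE
3,9,baseline,7.46,1.25,,,ok,FALSE
3,9,1,7.47,1.33,1,1,ok,FALSE
3,9,2,7.28,1.22,5,0,ok,FALSE
3,9,3,7.4,1.3,5,0,ok,FALSE
3,9,4,7.3,1.72,0,1,ok,TRUE
3,10,baseline,7.49,1.39,,,ok,FALSE
3,10,1,7.01,0.87,2,0,ok,FALSE
3,10,2,7.3,1.48,1,1,ok,FALSE
3,10,3,7.29,1.4,3,0,ok,FALSE
3,10,4,7.39,1.37,0,0,ok,FALSE
3,11,baseline,7.44,1.39,,,ok,FALSE
3,11,1,7.29,1.32,0,0,ok,FALSE
3,11,2,7.29,1.27,3,3,ok,FALSE
3,11,3,,,1,3,missing,FALSE
3,11,4,,,0,0,missing,FALSE
3,12,baseline,7.44,1.33,,,ok,FALSE
3,12,1,7.29,1.23,1,0,ok,FALSE
3,12,2,,,0,0,missing,FALSE
3,13,baseline,7.43,1.47,,,ok,FALSE
3,13,1,7.26,1.23,0,0,ok,FALSE
3,13,2,7.14,1.27,3,2,ok,FALSE
3,13,3,,,0,0,missing,FALSE
3,14,baseline,7.45,1.36,,,ok,FALSE
3,14,1,7.35,1.24,0,0,ok,FALSE
3,14,2,7.48,1.18,0,0,ok,FALSE
3,14,3,7.47,1.11,0,0,ok,FALSE
3,14,4,,,0,0,missing,FALSE
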