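# Surveillance and survey counts for the London MSM HIV prevalence model
# (Greater London, 2012). Field names match voisynth::hiv_observations().
#
# ypop is the ONS mid-2012 estimate of London males in the 15-44 age band
# described by this surveillance model family; the published count is cited
# but not reproduced verbatim in the sources, so this value is approximate.
ypop: 2060000
# NATSAL: men reporting to be GUM-attending MSM, non-attending MSM, former
# MSM, out of all men interviewed
y_G: 7
y_N: 38
y_P: 10
y_NAT: 824
# SOPHID: prevalent diagnosed HIV-positive MSM accessing care
y_M: 8390
# HANDD: new GUM-clinic HIV diagnoses among MSM
y_H: 630
# GUMCAD testing cascade: attenders, no previous diagnosis, offered test,
# tested, diagnosed
g1: 35121
g2: 34187
g3: 30570
g4: 29529
g5: 855
# GUM Anon: positives among previously undiagnosed attenders surveyed
g_A: 4
g_AN: 85
# GMSHS venue survey: positives/denominators among previously undiagnosed
# GMSM and NGMSM
y_G_GM: 20
n_G_GM: 493
y_N_GM: 20
n_N_GM: 452
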