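label,transformation,mz,formula_printed,formula,rt_min,error_ppm_printed,mouse_liver_microsome,human_liver_microsome,mouse_plasma,note
M1,Amide hydrolysis,261.1961,C16H24N2O4,C16H24N2O,7.36,0.4,O,O,O,printed formula inconsistent with m/z; corrected to match 261.1961 and the amide-hydrolysis delta
M2,Desaturation + Oxidation,406.2125,C24H27N3O3,C24H27N3O3,10.07,0.2,-,-,O,
M3,Di-desaturation,388.2020,C24H31N3O2,C24H25N3O2,11.53,1.0,O,O,O,printed formula inconsistent with m/z; corrected to match 388.2020 and di-desaturation
M4,Oxidation,408.2282,C24H29N3O3,C24H29N3O3,11.99,0.0,O,O,O,
M5,Di-oxidation,424.2231,C24H29N3O4,C24H29N3O4,12.48,0.2,O,-,O,
M6,Di-oxidation,424.2231,C24H29N3O4,C24H29N3O4,13.46,1.9,-,-,O,
M7,Di-oxidation,424.2231,C24H29N3O4,C24H29N3O4,13.91,2.1,-,-,O,
M8,Oxidation,408.2282,C24H29N3O3,C24H29N3O3,14.00,0.2,O,O,O,
M9,Di-desaturation,388.2020,C24H31N3O2,C24H25N3O2,14.11,1.0,O,O,O,printed formula inconsistent with m/z; corrected to match 388.2020 and di-desaturation
M10,Di-oxidation,424.2231,C24H29N3O4,C24H29N3O4,14.29,0.2,-,-,O,
M11,Tri-oxidation,440.2180,C24H29N3O5,C24H29N3O5,14.41,0.7,O,-,O,
M12,Saturation,394.2489,C24H31N3O2,C24H31N3O2,15.37,1.0,-,-,O,
M13,Di-oxidation,424.2231,C24H29N3O4,C24H29N3O4,15.87,0.7,-,-,O,
M14,Desaturation + Oxidation,406.2125,C24H27N3O3,C24H27N3O3,16.04,1.0,-,-,O,
M15,Tri-oxidation,440.2180,C24H29N3O5,C24H29N3O5,16.54,1.4,-,-,O,
M16,Desaturation,390.2176,C24H27N3O2,C24H27N3O2,17.27,2.8,O,O,O,
M17,Oxidation,408.2282,C24H29N3O3,C24H29N3O3,17.76,2.0,O,O,O,
M18,Desaturation + Oxidation,406.2125,C24H27N3O3,C24H27N3O3,19.15,0.7,O,-,O,
M19,Desaturation + Oxidation,406.2125,C24H27N3O3,C24H27N3O3,21.02,0.7,-,-,O,
M20,Amide hydrolysis followed by carboxylation,276.1594,C16H21NO3,C16H21NO3,21.25,1.8,O,O,O,
Parent,Parent,392.2333,C24H29N3O2,C24H29N3O2,22.31,2.3,O,O,O,
M21,Amide hydrolysis followed by hydroxylation,262.1802,C16H23NO2,C16H23NO2,22.76,0.4,O,O,O,
M22,Oxidation,408.2282,C24H29N3O3,C24H29N3O3,24.04,1.2,O,O,O,
M23,Desaturation,390.2176,C24H27N3O2,C24H27N3O2,24.67,2.8,O,O,O,
M24,Oxidation,408.2282,C24H29N3O3,C24H29N3O3,25.90,0.7,O,-,O,
M25,Desaturation + Oxidation,406.2125,C24H27N3O3,C24H27N3O3,26.31,0.5,O,-,O,
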