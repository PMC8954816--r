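Package: dmpkid
Title: Exact-Mass Metabolite Identification, Bioanalytical Calibration and
    Non-Compartmental Pharmacokinetics for Small-Molecule DMPK Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational side of a discovery-stage drug
    metabolism and pharmacokinetics (DMPK) workflow on high-resolution
    LC-MS data: molecular-formula parsing and monoisotopic mass / adduct
    m/z / ppm arithmetic; enumeration of phase-I biotransformation chains
    and exact-mass annotation of centroided peak lists; localization of
    modifications to structural moieties from product-ion fragment shifts;
    differential detection of N-oxide metabolites via titanium(III)
    chloride reduction; weighted quadratic calibration curves with
    back-calculation, accuracy/precision, dilution-integrity and stability
    statistics; and non-compartmental analysis of intravenous-bolus
    concentration-time profiles (AUC, lambda-z, half-life, clearance, Vss)
    with Hamilton AUC-proportional plasma pooling and dose-proportionality
    assessment. Seeded generators simulate every input so the full
    pipeline is testable without instrument data. Ships a worked example
    on the NAMPT inhibitor Daporinad (FK866).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
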