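Package: crossring
Title: Mechanistic Prediction of Cross-Ring Fragments of Sodiated Glycans in CID
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cross-ring dissociation fragments of singly charged
    sodium-adducted (oligo)saccharides in collision-induced dissociation by
    enumerating the retro-aldol reaction network of the reducing-end hexose
    (ring opening, hydrogen shifts, beta-carbonyl C-C cleavage, secondary
    dissociation) with atom-level partition and 18O isotope-label tracking.
    Fragment tiers (major/minor/trace) are classified from bundled
    transition-state barrier data. Includes exact monoisotopic and nominal
    mass arithmetic, CID peak-list annotation and glycosidic-linkage calling,
    a geometric conformer-candidate screening toolkit (Cremer-Pople ring
    puckering, sodium-oxygen coordination numbers, ultrafast shape
    recognition), and seeded synthetic-data generators for spectra and
    conformer ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
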