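Package: fpronmr
Title: Fluorine-19 NMR Analysis of Fluoroproline Peptides: Relaxation,
    Binding Equilibria and Exchange Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 19F NMR observables of
    4-fluoroproline-containing polyproline peptides. Computes 19F
    longitudinal, transverse and proton-fluorine cross-relaxation rates
    from pairwise dipole-dipole plus chemical-shift-anisotropy theory,
    inverts steady-state heteronuclear NOEs and R1 values to rotational
    correlation times, fits inversion-recovery and echo decays and NOE
    build-up curves, solves peptide-SH3 binding equilibria (1:1 and 1:2
    stoichiometries), fits dissociation constants jointly to 19F and
    amide chemical-shift-perturbation titrations, extracts association
    rate constants from fast-exchange line broadening, classifies
    proline ring pucker from scalar couplings, and generates synthetic
    data sets with realistic noise for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
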