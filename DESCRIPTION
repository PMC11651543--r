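Package: epiunmask
Title: Differential Solvent Exposure Analysis of Two-State Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies protein residues that become solvent-exposed upon a
    conformational change, such as the proteolytic activation of Bacillus
    thuringiensis Vip3 insecticidal protoxins. Computes per-atom and
    per-residue solvent-accessible surface area by Shrake-Rupley quadrature,
    normalises residue areas to Gly-X-Gly reference values, classifies
    residues as exposed or buried, and detects becomes-exposed residues
    between two states with a dual-criterion (relative-ratio and
    absolute-area) consensus. Also provides side-chain distance geometry,
    binding-region inference from overlapping-fragment binding data,
    conservation mapping onto multiple sequence alignments, and the
    accompanying assay statistics: one-site saturation binding (Kd), probit
    dose-response (LC50 with Fieller fiducial limits), fold-change ratios and
    cytotoxicity summaries. Includes seeded synthetic-data generators for
    every input class so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
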