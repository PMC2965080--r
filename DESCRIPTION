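Package: gcodon
Title: Codon Usage Bias Under GC Mutational Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous-time Markov chain model of synonymous codon usage
    under GC mutational bias. Builds per-amino-acid synonymous substitution
    networks, solves equilibrium codon frequencies (closed form and numeric)
    as a function of the GC bias parameter B, reads codon-count data (CUTG
    species-summary files, CDS FASTA, TSV tables), and provides the
    statistical analysis suite: usage-vs-GC3 correlations, LOESS fits,
    Harvey-Collier nonlinearity tests, variance-explained summaries and a
    deviation screen. Includes a synthetic-data generator (model-exact and
    multinomial-noise panels, CDS emission, Gillespie sequence evolution)
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lmtest,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
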