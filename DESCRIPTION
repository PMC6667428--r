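Package: pairwiseSIR
Title: Pairwise SIR Models and Epidemic Thresholds on Clustered Regular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed pairwise (pair-approximation) SIR models for regular
    networks with clustering. Implements the classic unclustered closure, the
    simple clustered closure and a compact improved closure that conserves
    pair-level relations; integrates the closed five-dimensional systems;
    analyses the two-dimensional fast-variable (correlation) subsystems,
    including null clines, the invariant region, Bendixson divergence and
    quasi-equilibria; computes epidemic thresholds from the steady-state cubic
    equations and from first-order asymptotic expansions in the global
    clustering coefficient; and provides a comparison suite of alternative
    threshold formulas (Keeling's correlation equation, next-generation
    matrix, motif-closure and percolation expressions, and a household-model
    reproduction number).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
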