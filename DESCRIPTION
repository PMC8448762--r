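Package: hiertls
Title: Hierarchical TLS Decomposition of Macromolecular Disorder
Version: 0.1.0
Authors@R:
    person("hiertls", "developers", email = "hiertls@example.org", role = c("aut", "cre"))
Description: Re-factors the atomic displacement parameters (B-factors) of a
    refined macromolecular structure into a parsimonious hierarchy of
    rigid-body Translation-Libration-Screw (TLS) contributions at multiple
    length scales (chain, secondary structure, residue, backbone/sidechain)
    plus a per-atom residual level. Fitting alternates simplex optimization
    of normalized TLS matrices with elastic-net-penalized amplitude
    optimization under a decaying penalty schedule, so that disorder is
    assigned to the largest length scale consistent with the data. Reads and
    writes PDB and mmCIF structures with isotropic and anisotropic
    displacement parameters, and includes a synthetic-structure generator
    with known ground-truth disorder for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
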