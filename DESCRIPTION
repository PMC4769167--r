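Package: gatemodes
Title: Collective-Motion Gate-Opening Analysis for CLC Transporter Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Essential-dynamics analysis of Calpha trajectories of CLC
    Cl-/H+ exchange transporters and similar membrane proteins. Builds the
    Calpha covariance matrix of aligned trajectory segments, extracts ranked
    orthonormal collective modes, deforms a reference structure along each
    mode to a fixed RMSD, and counts the modes that widen gate residue pairs
    beyond a distance-change threshold. Per-segment counts from two
    conditions (e.g. wild type versus cross-linked) are compared with an
    exact Wilcoxon-Mann-Whitney test that handles the heavy ties of small
    integer counts. Also provides rigid-body (Kabsch) superposition, a
    sphere-fitting pore radius profiler with bottleneck location, plain-text
    structure/trajectory IO, and a synthetic homodimer generator with
    planted collective modes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
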