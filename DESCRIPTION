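Package: fragstitch
Title: Conserved-Binding Fragment Merging, Linking and Constrained Placement
Version: 0.1.0
Authors@R: person("Fragstitch", "Developers", role = c("aut", "cre"),
    email = "fragstitch@example.org")
Description: Combines crystallographic fragment hits into larger candidate
    molecules by stitching their atomic coordinates directly: rings are
    collapsed to centroid placeholders, positionally overlapping atoms are
    merged, disconnected parts are joined with short alkyl linkers, and the
    resulting chemistry is repaired (rectified).  Arbitrary candidate
    molecules can likewise be placed against the hits via a multistep
    maximum-common-substructure atom mapping.  Stitched conformers are
    energy-minimised in the protein pocket under hit-derived positional
    restraints whose weights are halved each cycle until the snapshot
    binding energy is negative, then profiled for protein-ligand
    interactions, scored and filtered for acceptability.  Includes readers
    and writers for SDF and PDB, covalent (warhead dummy-atom) handling, a
    command-line front end and a synthetic fixture generator.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
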