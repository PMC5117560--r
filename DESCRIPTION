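Package: moietyr
Title: Identification of Conserved Moieties in Metabolic Networks from Atom
    Transition Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies conserved moieties in metabolic networks by graph
    analysis of atom transition networks. Builds the directed multigraph of
    atom-to-atom transitions from reaction stoichiometry and per-reaction atom
    mappings (MDL RXN/MOL V2000 or a tabular transition format), partitions it
    into connected components, groups isomorphic components into moiety graphs,
    and derives nonnegative-integer moiety vectors in the left null space of
    the internal stoichiometric matrix. Composite conservation vectors are
    decomposed by an exact integer program; moieties are classified as
    internal, transitive or integrative; downstream utilities cover moiety
    subnetworks and atom- versus moiety-resolution isotopomer counting.
    Includes fully specified dopamine-pathway fixtures and a planted-moiety
    synthetic network generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
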