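Package: egosna
Title: Ego-Centric Social Network Analysis for Innovation Diffusion Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ego-centric (personal) network questionnaire
    data of the kind collected in innovation-diffusion field studies: a
    validated data model for egos, alters and symmetric communication ties;
    readers and writers for roster and tie files; per-network statistics
    (density, degree centrality, Brandes betweenness centrality, Freeman
    degree centralization) implemented from their definitions; Krackhardt-
    style E-I homophily indices and actor-level homophily summaries;
    descriptive tabulations; sociogram export to GraphML and DOT with
    attribute-driven node coding; and a seeded synthetic questionnaire-data
    generator with controllable attribute marginals, density and
    assortativity for pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
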