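Package: undesired
Title: Undesired-Child Classification and Under-Five Morbidity Modelling
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying "undesired" (unwanted) children and
    under-five morbidity with DHS-style survey microdata.  Classifies
    children and mothers as excess in boys, girls, parity or both, from
    stated fertility preferences (ideal numbers of boys, girls and
    either-gender children) and ordered birth histories; tabulates
    prevalence by background characteristics; runs a binary-association
    stage (tetrachoric correlation, KMO sampling adequacy, Bartlett
    sphericity, principal components); fits a multivariate probit model
    to correlated binary morbidity outcomes by GHK simulated maximum
    likelihood; and evaluates random-forest and neural-network
    classifiers with permutation and impurity variable importance.
    Because the survey microdata it targets are access-restricted, the
    package ships a synthetic-population generator with known ground
    truth (latent-Gaussian correlated binary outcomes) so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
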