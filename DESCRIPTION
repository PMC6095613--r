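Package: avpid
Title: Partial Information Decomposition of Audiovisual Speech Entrainment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian-copula estimation of mutual information between
    band-limited phase signals and a partial information decomposition (PID)
    of the information two dynamic speech features -- the auditory amplitude
    envelope and the speaker's lip area -- carry about a neural signal.
    Redundancy is measured by the pointwise common change in surprisal (Iccs)
    under a maximum-entropy trivariate surrogate, integrated by Monte Carlo;
    unique and synergistic terms follow from the PID identities. Includes the
    supporting signal processing (cochlear-band envelope extraction, zero-phase
    band-pass filtering, analytic-signal phase representations, stimulus-brain
    lag alignment), spectral and delayed mutual-information profiles,
    time-shift surrogate normalisation, permutation group contrasts and
    behavior regression with FDR control, and a synthetic-data generator that
    plants redundant, unique and synergistic stimulus-brain coupling with a
    behavioral link for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
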