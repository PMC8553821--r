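# Reduced-size Monte Carlo settings for unit tests; acceptance tests use
# the full default run length.
fastClutch <- function(...) ClutchParams(nSteps = 20000L, ...)

# independent logistic evaluation of the binding-rate law, kept deliberately
# separate from the package implementation
konOracle <- function(E, h, kMin = 0.05, kMax = 1, eS = 7e3, eH = 18e3,
                      s = 2) {
  eHalf <- eS^(1 - h) * eH^h
  kMin + (kMax - kMin) / (1 + exp(-s * (log(E) - log(eHalf))))
}
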