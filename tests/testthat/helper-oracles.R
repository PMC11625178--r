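# Independent hand-arithmetic oracles: each restates the published
# evaluation equation directly, so the quantifier implementations are
# checked against a second, separate transcription.

oracleHarboe <- function(a380, a415, a450, df = 1)
  df * 0.155 * (83.6 * (2 * a415 - a380 - a450))

# combined estimator at DF = 1, where the printed formula is parse-invariant
oracleEq1Df1 <- function(a400, cHb)
  25.64 * a400 - 2.59 * cHb + 4.85

oraclePyridineEps <- function(a, epsMM, path = 1, df = 1)
  df * (a / (epsMM * path)) * 1000 # mM -> uM

oracleApoHrpFromHb <- function(cHbNm)
  3.629 * cHbNm + 21.86

oracleDirectHeme <- function(a380, df = 1) df * (a380 + 0.170) / 0.029
oracleDirectHb <- function(a405, df = 1) df * (a405 + 0.007) / 0.158

relErr <- function(got, expected)
  abs(got - expected) / pmax(abs(expected), .Machine$double.eps)
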