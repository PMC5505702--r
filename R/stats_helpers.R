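# Shared test helpers.
#
# Mann-Whitney policy: exact null enumeration when both groups have at most
# 8 observations and there are no ties; otherwise the midrank normal
# approximation with continuity correction (stats::wilcox.test supplies
# both paths).

mwu_p <- function(x, y, alternative = "greater") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  if (length(unique(c(x, y))) == 1) return(1)  # fully tied: no evidence
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= 8 && length(y) <= 8
  suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                      exact = use_exact,
                                      correct = TRUE)$p.value)
}

# exact one-sample sign test against a constant reference (values equal to
# the reference are dropped, the standard conditioning)
sign_test_p <- function(x, mu = 1, alternative = "greater") {
  x <- x[!is.na(x)]
  n <- sum(x != mu)
  if (n == 0) return(1)
  stats::binom.test(sum(x > mu), n, p = 0.5,
                    alternative = alternative)$p.value
}
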