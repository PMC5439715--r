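# LQ parameters solved through the two published survival points
# (S(8 Gy) = 2.55%, S(16 Gy) = 0.009%); recomputed from scratch here so tests
# carry their own oracle rather than trusting the package's interpolation.
lq_oracle <- function() {
  A <- rbind(c(8, 64), c(16, 256))
  ab <- solve(A, -log(c(0.0255, 0.00009)))
  list(alpha = ab[[1]], beta = ab[[2]])
}

# Brute-force quantile normalization: rank-average with ties sharing the
# mean of tied ranks. Independent of limma.
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # fractional ranks (ties) interpolate between adjacent reference values
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    lo + (r - floor(r)) * (hi - lo)
  })
}
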