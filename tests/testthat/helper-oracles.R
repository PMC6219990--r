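# independent oracle: full enumeration of all 2^n sign assignments of the
# paired Wilcoxon signed-rank test
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_lo <- mean(ws <= w_obs + 1e-9)
  p_hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}
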