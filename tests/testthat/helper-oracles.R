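## enumeration oracle: exact two-sided signed-rank p over all 2^n sign
## assignments of the observed absolute differences (mid-ranks kept fixed)
enumWilcoxP <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- signs %*% r
  pLe <- mean(Vs <= V + 1e-12)
  pGe <- mean(Vs >= V - 1e-12)
  min(1, 2 * min(pLe, pGe))
}
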