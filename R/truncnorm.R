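# Tail-safe truncated-normal draws and stable normal-interval log probabilities.
# Both work on standardized endpoints; reflection keeps all CDF evaluations in
# the lower tail, where p underflows gracefully instead of saturating at 1.

# Draw from N(0,1) truncated to (lo, hi), elementwise; inverse-CDF method so
# the draw is a deterministic function of one uniform per element.
rtnorm_std <- function(lo, hi, u = stats::runif(length(lo))) {
  flip <- is.finite(lo) & lo >= 0
  l <- ifelse(flip, -hi, lo)
  h <- ifelse(flip, -lo, hi)
  pl <- stats::pnorm(l)
  ph <- stats::pnorm(h)
  q <- stats::qnorm(pl + u * (ph - pl))
  # far-tail degeneracy: interval mass underflows; fall back to the finite edge
  bad <- !is.finite(q)
  if (any(bad)) q[bad] <- ifelse(is.finite(l[bad]), l[bad], h[bad])
  ifelse(flip, -q, q)
}

# log[Phi(hi) - Phi(lo)] elementwise, stable when both endpoints sit in the
# same tail. Probabilities are floored at 1e-300; the number of floored terms
# is returned as an attribute so callers can flag degenerate states.
log_pnorm_diff <- function(lo, hi) {
  flip <- is.finite(lo) & lo >= 0
  l <- ifelse(flip, -hi, lo)
  h <- ifelse(flip, -lo, hi)
  la <- stats::pnorm(h, log.p = TRUE)
  lb <- stats::pnorm(l, log.p = TRUE)
  out <- ifelse(is.finite(lb), la + log1p(-pmin(exp(lb - la), 1)), la)
  floor_log <- log(1e-300)
  n_floored <- sum(out < floor_log | !is.finite(out))
  out <- pmax(out, floor_log)
  attr(out, "n_floored") <- n_floored
  out
}
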