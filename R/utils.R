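# Internal numerical helpers. Everything downstream works in log space:
# population sizes can exceed 1e6, where direct products of binomial pmfs
# underflow double precision.

logsumexp <- function(lx) {
  lx <- lx[!is.na(lx)]
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

stop_domain <- function(msg, ...) {
  abort(msg, class = "popsize_domain_error", ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = "popsize_parse_error", ...)
}
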