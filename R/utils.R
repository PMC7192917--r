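# shared internal helpers

# Spearman rho with average ranks on finite pairs; NA when degenerate.
.spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# locale-independent lexicographic sort (C collation via radix)
.lexSort <- function(x) sort(x, method = "radix")

# canonical key for a gene set, used for deterministic tie-breaking
.setKey <- function(s) paste(.lexSort(s), collapse = "\r")
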