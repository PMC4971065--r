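# internal numeric helpers

# center a vector and scale to unit norm (returns zeros for constant input)
.unitMap <- function(v) {
  v <- v - mean(v)
  s <- sqrt(sum(v^2))
  if (s > 0) v / s else v
}

# average-reference rows of a maps matrix (rows = topographies)
.centerRows <- function(M) M - rowMeans(M)

# rows centered and unit-norm; zero rows stay zero
.unitRows <- function(M) {
  M <- .centerRows(M)
  s <- sqrt(rowSums(M^2))
  s[s == 0] <- 1
  M / s
}

# last-observation-carried-forward for integer vectors with NA gaps;
# leading NAs take the first non-NA value
.locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  first <- which(ok)[1L]
  idx[idx == 0L] <- first
  x[idx]
}

.stateNamesFor <- function(K) {
  if (K <= 26) LETTERS[seq_len(K)] else paste0("S", seq_len(K))
}
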