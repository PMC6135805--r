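# shared internal helpers

# canonical protein/gene set: sorted unique character vector
.asSet <- function(x) {
  x <- as.character(x)
  sort(unique(x[!is.na(x) & x != ""]))
}

# derive a module-level sub-seed from the study seed; stays below 2^31
.subSeed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 1000003) * 2017 + 13 * k) %% 2147483629)
}

# one-way R^2 of a numeric response on a factor
.onewayR2 <- function(y, f) {
  f <- factor(f)
  if (nlevels(f) < 2) return(0)
  gm <- mean(y)
  sst <- sum((y - gm)^2)
  if (sst == 0) return(0)
  m <- tapply(y, f, mean)
  n <- tabulate(f)
  ssb <- sum(n * (m - gm)^2)
  ssb / sst
}
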