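# Internal helpers shared across the package.

# Clamp p-values away from 0/1 before inverse-normal transforms.
clamp_p <- function(p, eps = 1e-16) pmin(pmax(p, eps), 1 - eps)

# Vectorised bytewise (C-collation) string comparison, independent of the
# session locale: ranks both vectors against radix-sorted levels.
str_lt <- function(a, b) {
  levs <- sort(unique(c(a, b)), method = "radix")
  match(a, levs) < match(b, levs)
}

# Unordered pair key; node ids are opaque strings, compared bytewise.
pair_key <- function(a, b) {
  swap <- str_lt(b, a)
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic string sort (C collation, independent of locale).
sort_c <- function(x) sort(x, method = "radix")

# Bytewise string comparison, independent of locale collation.
lt_c <- function(a, b) {
  if (a == b) return(FALSE)
  sort(c(a, b), method = "radix")[1L] == a
}

new_seed_stream <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
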