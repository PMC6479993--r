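# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed (< 2^31) from a parent seed and a sequence
# of integer tags, so one pipeline seed fans out to independent stage seeds.
child_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + abs(as.numeric(k)) + 1) %% 2147483647
  as.integer(h)
}

# Accuracy as the percentage convention used in reports: two decimals.
accuracy_pct <- function(correct, total) round(100 * correct / total, 2)

# One-hot (dummy) coding of class labels against an explicit class list.
onehot <- function(y, classes = sort(unique(y))) {
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, as.character(classes)))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
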