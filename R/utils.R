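# Small shared helpers. Internal only.

# Population standard deviation (divide by n, not n-1). Used wherever a
# whole-structure or whole-group distribution is summarized rather than
# estimated from a sample.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Euclidean distances from one point to a matrix of points.
dist_to_point <- function(coords, p) {
  sqrt((coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2 + (coords[, 3] - p[3])^2)
}

# Minimum Euclidean distance between two coordinate matrices (n x 3, m x 3).
min_cross_dist <- function(a, b) {
  # cross squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab'
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

# Stable short hash of a character vector (used for feature-layout checks).
layout_hash <- function(x) {
  s <- paste(x, collapse = "|")
  v <- utf8ToInt(s)
  h <- 5381
  for (c in v) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x-%d", h, length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
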