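#' @keywords internal
"_PACKAGE"

#' @importFrom stats var cov sd rnorm runif rlnorm rmultinom rgamma
#'   median cor.test coef lm setNames p.adjust pt
#'   weighted.mean as.dist hclust
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_invalid(...)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Stages of the pipeline draw random numbers independently; each stage seeds
#' its own RNG with a sub-seed derived deterministically from the master seed
#' and a short stage tag, so adding randomness to one stage never perturbs
#' another. Values stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param tag character tag naming the consumer (e.g. "counts", "pair:17").
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  # multiplicative string hash kept below 2^31 (exact in double arithmetic)
  h <- 5381
  for (ch in utf8ToInt(paste0(tag, ":", format(seed)))) {
    h <- (h * 69069 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' Evaluate code under a local RNG seed
#'
#' Sets the RNG seed, evaluates \code{code}, and restores the caller's RNG
#' state, so seeded draws never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Short deterministic hex identifier for a string (used for ASV ids).
hex_hash <- function(x, nchar_out = 16L) {
  stopifnot(nchar_out %% 8L == 0L)
  out <- character(length(x))
  for (k in seq_along(x)) {
    pieces <- vapply(seq_len(nchar_out / 8L), function(salt) {
      h <- 5381 + salt * 97
      for (ch in utf8ToInt(x[[k]])) {
        h <- (h * 69069 + ch + salt) %% 2147483647
      }
      sprintf("%08x", as.integer(h))
    }, character(1))
    out[[k]] <- paste(pieces, collapse = "")
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of planted module structure by network clustering.
#'
#' @param a,b membership vectors over the same elements (any label type).
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) > 0,
              "partitions must be non-empty and of equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# Spearman rank correlation with p-value, small wrapper used in several places.
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  ct <- stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
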