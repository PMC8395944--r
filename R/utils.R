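#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stage seeds are a deterministic function of the global seed and the stage
#' name, so toggling one pipeline stage does not shift the random stream of
#' any other stage. The result is always a valid 32-bit R seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, implemented directly (monotone
#' cumulative minimum of `p * n / rank` from the largest p downward).
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`s propagate.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (n == 0L) return(out)
  o <- ok[order(p[ok], decreasing = TRUE)]
  adj <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  out[o] <- adj
  out
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to renaming), about 0 for independent ones.
#'
#' @param a,b Vectors of equal length interpretable as cluster labels.
#' @return A single numeric value (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# most frequent value of an integer vector; random tie-break using the
# current RNG stream (callers seed it)
.mode_label <- function(x) {
  ux <- unique(x)
  if (length(ux) == 1L) return(ux)
  cnt <- tabulate(match(x, ux))
  win <- ux[cnt == max(cnt)]
  if (length(win) == 1L) win else win[sample.int(length(win), 1L)]
}
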