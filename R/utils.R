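## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Dense ranks, largest value gets rank 1, ties share a rank.
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

## Area under the precision-recall curve as average precision:
## mean over positives of precision at each positive's rank.
## Ties in `score` are averaged by random-free ordering on the label
## (pessimistic: negatives first within a tie would inflate nothing; we
## use the conventional ordering by decreasing score with ties broken
## by decreasing label so equal-scored positives are not penalised
## arbitrarily; with continuous scores ties are immaterial).
auprc <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.integer(label != 0)
  ord <- order(score, label, decreasing = TRUE)
  lab <- label[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  if (sum(lab) == 0L) return(NA_real_)
  sum(precision[lab == 1L]) / sum(lab)
}

## Inverse of the trigamma function by Newton iteration on 1/trigamma,
## which is nearly linear; used by the empirical-Bayes variance prior fit.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

## Run code with a temporary RNG state seeded from `seed`, restoring the
## caller's .Random.seed afterwards so generators do not disturb sessions.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
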