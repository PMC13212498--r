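#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

# Benjamini-Hochberg with NA pass-through; NAs (untestable features) are
# excluded from the denominator so they cannot deflate the thresholds.
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

geometric_mean <- function(x) exp(mean(log(x)))

# Batch ordinary least squares against a shared design matrix.
#
# Solves the normal equations once per design and reports two-sided t-tests
# for every coefficient and every response column. Returns NULL when the
# design is rank deficient (callers flag the feature as untestable).
ols_batch <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  q <- ncol(X)
  n <- nrow(X)
  if (n <= q) return(NULL)
  if (qr(X)$rank < q) return(NULL)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  B <- backsolve(R, backsolve(R, crossprod(X, Y), transpose = TRUE))
  fitted <- X %*% B
  rss <- colSums((Y - fitted)^2)
  df <- n - q
  # floor keeps t well-defined for exact fits (constant y -> t ~ 0, p ~ 1)
  sigma2 <- pmax(rss / df, 1e-24)
  xtx_inv_diag <- diag(chol2inv(R))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- B / se
  pval <- 2 * stats::pt(-abs(tval), df)
  dimnames(B) <- list(colnames(X), colnames(Y))
  dimnames(se) <- dimnames(tval) <- dimnames(pval) <- dimnames(B)
  list(beta = B, se = se, t = tval, p = pval, df = df, sigma2 = sigma2)
}

# Derive a child RNG seed from a base seed and a stage offset, kept within
# the 32-bit integer range R requires.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483563) + 1L
}

format_num <- function(x) formatC(x, digits = 15, format = "g")
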