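#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Rank-sum comparison of two samples. For small groups (both sizes at most
#' `exact_max`) the null distribution of U is obtained by complete enumeration
#' of all group assignments, which handles ties without approximation. For
#' larger groups a normal approximation with tie correction and continuity
#' correction is used.
#'
#' The U statistic counts pairs where an `x` value exceeds a `y` value, with
#' ties contributing 1/2. Two-sided exact p-values are computed as
#' `min(1, 2 * min(P(U <= u), P(U >= u)))` over the enumerated distribution.
#'
#' @param x,y numeric vectors (the two groups).
#' @param alternative "two.sided", "greater" (x tends larger), or "less".
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   (`NULL`) enumerates when both groups have at most `exact_max` values.
#' @param exact_max group-size bound for the exact path.
#' @return list with `statistic` (U for `x`), `p.value`, and `method`.
#' @export
mw_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                    exact = NULL, exact_max = 8L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x[is.finite(x)])
  y <- as.numeric(y[is.finite(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("mw_test: both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  do_exact <- if (is.null(exact)) (n1 <= exact_max && n2 <= exact_max) else exact

  if (do_exact) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    m <- length(u_all)
    p_le <- sum(u_all <= u_obs + 1e-9) / m
    p_ge <- sum(u_all >= u_obs - 1e-9) / m
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater   = p_ge,
      less      = p_le)
    return(list(statistic = u_obs, p.value = p, method = "exact enumeration"))
  }

  N <- n1 + n2
  ties <- table(pooled)
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    # all values identical: no evidence either way
    return(list(statistic = u_obs, p.value = 1,
                method = "normal approximation"))
  }
  sigma <- sqrt(sigma2)
  d <- u_obs - mu
  p <- switch(alternative,
    two.sided = {
      cc <- sign(d) * 0.5
      2 * stats::pnorm(abs((d - cc) / sigma), lower.tail = FALSE)
    },
    greater = stats::pnorm((d - 0.5) / sigma, lower.tail = FALSE),
    less    = stats::pnorm((d + 0.5) / sigma, lower.tail = TRUE))
  list(statistic = u_obs, p.value = min(1, p),
       method = "normal approximation with tie correction")
}

#' Empirical cumulative distribution as point pairs
#'
#' @param x numeric vector.
#' @return data.frame with columns `x` (sorted unique values) and `F`
#'   (cumulative probability at each value).
#' @export
ecdf_points <- function(x) {
  x <- sort(x[is.finite(x)])
  if (length(x) == 0L) return(data.frame(x = numeric(0), F = numeric(0)))
  ux <- unique(x)
  data.frame(x = ux, F = cumsum(tabulate(match(x, ux))) / length(x))
}
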