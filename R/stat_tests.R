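# Rank-based tests implemented from first principles, with exact
# enumeration at small sample sizes and tie-corrected large-sample
# approximations otherwise.

#' All permutations of 1..n
#' @noRd
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    block <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Tie-correction term sum(t^3 - t) over tie groups
#' @noRd
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For total sample sizes up to 12 the p-value is
#' exact, by enumeration of all assignments of the pooled ranks to the two
#' groups; above that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_max Largest pooled n for which enumeration is used.
#' @return List with `U` (the smaller of the two U statistics), `p`
#'   (two-sided) and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney_u <- function(a, b, exact_max = 12L) {
  if (length(a) < 1L || length(b) < 1L) bt_stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- midrank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  u <- min(u_a, u_b)
  if (n <= exact_max) {
    idx <- utils::combn(n, na)
    ranksum <- colSums(matrix(r[idx], nrow = na))
    ua_perm <- ranksum - na * (na + 1) / 2
    u_perm <- pmin(ua_perm, na * nb - ua_perm)
    p <- mean(u_perm <= u + 1e-9)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term(r) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
    z <- (u - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal"
  }
  list(U = u, p = p, method = method)
}

#' All assignments of positions into labeled groups of given sizes
#' @noRd
enum_assignments <- function(pos, sizes) {
  if (length(sizes) == 1L) return(list(list(pos)))
  out <- list()
  for (f in utils::combn(pos, sizes[1L], simplify = FALSE)) {
    for (rest in enum_assignments(setdiff(pos, f), sizes[-1L])) {
      out[[length(out) + 1L]] <- c(list(f), rest)
    }
  }
  out
}

#' @noRd
kw_statistic <- function(r, groups_idx, n) {
  correction <- 1 - tie_term(r) / (n^3 - n)
  if (correction <= 0) return(0)
  rbar <- vapply(groups_idx, function(i) mean(r[i]), numeric(1))
  ng <- lengths(groups_idx)
  h <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
  h / correction
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic. For total n up to `exact_max` (default 10) the
#' p-value is exact, by enumeration of all assignments of observations to
#' the group sizes; otherwise it is taken from the chi-squared reference
#' distribution with k-1 degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param class_labels Group label per observation (at least 2 groups).
#' @param exact_max Largest total n for which enumeration is used.
#' @return List with `H`, `p` and `method`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, class_labels, exact_max = 10L) {
  class_labels <- as.character(class_labels)
  groups <- split(seq_along(values), class_labels)
  if (length(groups) < 2L) bt_stop("kruskal_wallis needs at least 2 classes")
  if (any(lengths(groups) < 1L)) bt_stop("every class needs at least 1 observation")
  n <- length(values)
  r <- midrank(values)
  h <- kw_statistic(r, groups, n)
  if (n <= exact_max) {
    sizes <- lengths(groups)
    h_perm <- vapply(enum_assignments(seq_len(n), sizes),
                     function(a) kw_statistic(r, a, n), numeric(1))
    p <- mean(h_perm >= h - 1e-9)
    method <- "exact"
  } else {
    p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
    method <- "chisq"
  }
  list(H = h, p = p, method = method)
}

#' Spearman correlation with a permutation p-value
#'
#' Correlation of midranks (ties averaged), with a two-sided permutation
#' p-value: exact enumeration over all n! rank permutations when n <= 7,
#' Monte-Carlo with the +1/+1 convention otherwise. No time lag is applied
#' to either series. A constant series makes r undefined; such pairs are
#' returned with `degenerate = TRUE` and p = 1 so they can never be called
#' significant.
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @param n_permutations Monte-Carlo permutations when n > 7.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return List with `r`, `p`, `method` and `degenerate`.
#' @export
#' @examples
#' spearman_perm(1:5, c(2, 4, 6, 8, 10)) # r = 1, exact p = 2/120
spearman_perm <- function(x, y, n_permutations = 999L, seed = NULL) {
  if (length(x) != length(y)) bt_stop("series must have equal length")
  n <- length(x)
  if (n < 5L) bt_stop("series must have length >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = 1, method = "degenerate", degenerate = TRUE))
  }
  rx <- midrank(x); ry <- midrank(y)
  sx <- (rx - mean(rx)) / stats::sd(rx)
  sy <- (ry - mean(ry)) / stats::sd(ry)
  r_obs <- sum(sx * sy) / (n - 1)
  if (n <= 7L) {
    perm <- all_perms(n)
    sy_perm <- matrix(sy[perm], nrow(perm), n)
    r_perm <- as.vector(sy_perm %*% sx) / (n - 1)
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-9)
    method <- "exact"
  } else {
    r_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        sum(sx * sy[sample.int(n)]) / (n - 1)
      }, numeric(1))
    })
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-9)) / (1 + n_permutations)
    method <- "permutation"
  }
  list(r = r_obs, p = p, method = method, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_(j>=i) (p_(j) * m / j)`, capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) bt_stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Bonferroni correction
#'
#' @param p Vector of p-values.
#' @return `min(1, p * m)` for each p.
#' @export
bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) bt_stop("p-values must lie in [0, 1]")
  pmin(1, p * length(p))
}
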