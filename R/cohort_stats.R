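#' Ultimate stress and strain of a specimen
#'
#' Extracts the rupture-point summary from an *untruncated* stress-stretch
#' curve (loading continued until the specimen separated): the ultimate
#' stress is the maximum stress over the curve (not necessarily the last
#' point) and the ultimate strain is the engineering strain at the last
#' recorded point, `lambda_last - 1`.
#'
#' @param curve a non-empty [tensile_curve()], pre-plateau truncation.
#' @return a list with `specimen_id`, `ultimate_strain`, `ultimate_stress`.
#' @export
extract_ultimates <- function(curve) {
  stopifnot(inherits(curve, "tensile_curve"))
  if (length(curve$stretch) == 0L) abort_validation("empty curve")
  list(specimen_id = curve$specimen_id,
       ultimate_strain = curve$stretch[length(curve$stretch)] - 1,
       ultimate_stress = max(curve$stress))
}

#' Exact Mann-Whitney U test for small samples
#'
#' Computes the Mann-Whitney U statistic from (mid-)rank sums and its exact
#' p-value by complete enumeration of all `choose(n1 + n2, n1)` group
#' assignments of the observed ranks. The enumeration is carried out as a
#' subset-sum dynamic programme over the (doubled, hence integer) mid-ranks,
#' which is the full-assignment count factored by rank-sum; ties are handled
#' by mid-ranks with no continuity or normal approximation anywhere.
#'
#' U is reported for `group_a`: `U = W_a - n1 (n1 + 1) / 2` where `W_a` is
#' the rank sum of `group_a`. The two-sided p-value is the exact probability
#' of `|U - n1 n2 / 2| >=` the observed deviation; `"greater"` means
#' `group_a` tends to larger values (`P(U >= U_obs)`), `"less"` the reverse.
#'
#' @param group_a,group_b non-empty numeric vectors (each of size 1..12 --
#'   the exact-enumeration regime).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return an object of class `mw_test_result`: `U`, `p_value`,
#'   `alternative`, `method = "exact"`, `n1`, `n2`.
#' @examples
#' mann_whitney_exact(c(1.05, 1.01, 1.00, 0.38, 0.33),
#'                    c(1.10, 1.13, 1.75))
#' @export
mann_whitney_exact <- function(group_a, group_b,
                               alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L) {
    abort_validation("both groups must be non-empty")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort_validation("group values must be finite")
  }
  n1 <- length(a); n2 <- length(b)
  if (n1 > 12L || n2 > 12L) {
    abort_validation("exact enumeration supports group sizes up to 12")
  }
  r2 <- as.integer(round(2 * rank(c(a, b))))  # doubled mid-ranks: integers
  w2_obs <- sum(r2[seq_len(n1)])
  u_obs <- w2_obs / 2 - n1 * (n1 + 1) / 2

  # ways[k+1, s+1] = number of size-k subsets of r2 with doubled-rank sum s
  total <- sum(r2)
  ways <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  ways[1L, 1L] <- 1
  for (r in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      nz <- which(ways[k, ] > 0)
      if (length(nz)) {
        ways[k + 1L, nz + r] <- ways[k + 1L, nz + r] + ways[k, nz]
      }
    }
  }
  counts <- ways[n1 + 1L, ]
  s2 <- which(counts > 0) - 1L
  cnt <- counts[counts > 0]
  u_all <- s2 / 2 - n1 * (n1 + 1) / 2
  n_assign <- choose(n1 + n2, n1)
  mu <- n1 * n2 / 2
  eps <- 1e-9
  p <- switch(alternative,
    two_sided = sum(cnt[abs(u_all - mu) >= abs(u_obs - mu) - eps]) / n_assign,
    greater = sum(cnt[u_all >= u_obs - eps]) / n_assign,
    less = sum(cnt[u_all <= u_obs + eps]) / n_assign)
  structure(list(U = u_obs, p_value = p, alternative = alternative,
                 method = "exact", n1 = n1, n2 = n2),
            class = "mw_test_result")
}

#' @export
print.mw_test_result <- function(x, ...) {
  cat(sprintf("<mw_test_result> exact Mann-Whitney: U = %g (n1 = %d, n2 = %d), %s p = %.6g\n",
              x$U, x$n1, x$n2, x$alternative, x$p_value))
  invisible(x)
}

#' Cohort comparison report
#'
#' Runs the exact Mann-Whitney test on a named quantity for two groups and
#' returns a tidy one-row-per-group report plus the test.
#'
#' @param values named numeric vector (names are specimen ids).
#' @param groups named character vector mapping specimen id to group.
#' @param group_a,group_b the two group labels to compare (a vs b).
#' @param alternative passed to [mann_whitney_exact()].
#' @return list with `table` (group, n, median) and `test`
#'   (a `mw_test_result`).
#' @export
compare_cohorts <- function(values, groups, group_a, group_b,
                            alternative = "two_sided") {
  ids <- names(values)
  if (is.null(ids)) abort_validation("`values` must be named by specimen id")
  ga <- values[ids[groups[ids] == group_a]]
  gb <- values[ids[groups[ids] == group_b]]
  if (length(ga) == 0L || length(gb) == 0L) {
    abort_validation(sprintf("need at least one specimen in each of '%s' and '%s'",
                             group_a, group_b))
  }
  test <- mann_whitney_exact(ga, gb, alternative)
  list(table = data.frame(group = c(group_a, group_b),
                          n = c(length(ga), length(gb)),
                          median = c(stats::median(ga), stats::median(gb))),
       test = test)
}
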