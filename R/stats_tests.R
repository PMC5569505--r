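# Nonparametric two-group comparison used for the domain-level gene-family
# contrasts: Mann-Whitney U with an exact permutation null for small
# groups (handles ties by construction) and a tie-corrected normal
# approximation otherwise, followed by Bonferroni adjustment.

# U statistic for group x vs group y (number of (i,j) pairs with
# x_i > y_j, ties counting 1/2)
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' Uses the exact permutation null (full enumeration of all
#' `choose(n1 + n2, n1)` group assignments, valid under ties) whenever
#' `min(n1, n2) <= exact_min_n` and the enumeration stays below
#' `max_enumeration` splits; otherwise the normal approximation with tie
#' correction and continuity correction. The two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`. Constant data across both
#' groups gives p = 1.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_min_n exact-null size gate (default 8).
#' @param max_enumeration largest enumeration attempted (default 2e5).
#' @return list: U (for the first group), p_value, method ("exact" or
#'   "normal").
#' @export
mann_whitney <- function(x, y, exact_min_n = 8, max_enumeration = 2e5) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  u <- u_statistic(x, y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(U = u, p_value = 1, method = "degenerate"))
  n_splits <- choose(n1 + n2, n1)
  if (min(n1, n2) <= exact_min_n && n_splits <= max_enumeration) {
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(ii) u_statistic(pooled[ii], pooled[-ii]))
    eps <- 1e-9
    p_lo <- mean(us <= u + eps)
    p_hi <- mean(us >= u - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = u, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  r <- rank(pooled)
  ties <- table(r)
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u, p_value = 1, method = "degenerate"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = u, p_value = p, method = "normal")
}

#' Per-family domain comparison with Bonferroni correction
#'
#' For each gene family, a two-sided Mann-Whitney test on per-MAG counts
#' between the two domains; p-values are Bonferroni-adjusted over the
#' number of families tested and called significant below `alpha`.
#'
#' @param counts data.frame: mag_id, family_id, count (MAGs absent for a
#'   family count as 0).
#' @param groups data.frame: mag_id, domain (exactly two domain levels).
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame: family_id, mean per domain, U, p_raw, p_adj,
#'   significant.
#' @export
domain_comparison_test <- function(counts, groups, alpha = 0.05) {
  groups <- groups[!duplicated(groups$mag_id), ]
  doms <- sort(unique(groups$domain))
  if (length(doms) != 2) stop("need exactly two domains")
  if (any(table(groups$domain) < 2)) stop("need >= 2 MAGs per domain")
  fams <- sort(unique(counts$family_id))
  wide <- matrix(0, nrow(groups), length(fams),
                 dimnames = list(groups$mag_id, fams))
  wide[cbind(match(counts$mag_id, groups$mag_id),
             match(counts$family_id, fams))] <- counts$count
  g1 <- groups$domain == doms[1]
  res <- lapply(fams, function(f) {
    x <- wide[g1, f]; y <- wide[!g1, f]
    mw <- mann_whitney(x, y)
    data.frame(family_id = f, mean_1 = mean(x), mean_2 = mean(y),
               U = mw$U, p_raw = mw$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", doms)
  out$p_adj <- p.adjust(out$p_raw, method = "bonferroni")
  out$significant <- out$p_adj < alpha
  out
}
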