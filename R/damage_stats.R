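#' Rank atom types by mean density loss, per dataset and across datasets
#'
#' For each atom type (residue name, atom name), the mean raw D_loss over
#' all atoms of that type is computed per dataset, and types are ranked by
#' descending mean: rank 0 is the most damaged type in that dataset. For
#' series with several higher-dose datasets, the products of the per-dataset
#' ranks are then ranked (ascending product, rank 0 = smallest product) to
#' give an across-dataset rank. Note a type ranked 0 in any single dataset
#' has product 0: a faithful consequence of the scheme. Ties (in means or
#' products) are broken by the mean of the per-dataset ranks, then by
#' lexicographic atom-type key; this policy is recorded in the result.
#'
#' @param tab A D_loss table (see \code{\link{run_series}}).
#' @param keys List of \code{atom_type_key}s defining the ranking universe.
#'   Keys absent from the table are excluded and reported in
#'   \code{attr(,"absent")}.
#' @return A \code{rank_table}: data.frame with one row per present key
#'   (resname, atom, mean_<dataset>..., rank_<dataset>..., rank_product,
#'   rank_overall).
#' @export
rank_atom_types <- function(tab, keys) {
  datasets <- unique(tab$dataset)
  if (length(datasets) == 0) stop("no datasets in D_loss table")
  kdf <- data.frame(
    resname = vapply(keys, `[[`, "", "resname"),
    atom = vapply(keys, `[[`, "", "atom"), stringsAsFactors = FALSE)
  present <- mapply(function(r, a) any(tab$resname == r & tab$atom == a),
                    kdf$resname, kdf$atom)
  absent <- kdf[!present, , drop = FALSE]
  kdf <- kdf[present, , drop = FALSE]
  if (nrow(kdf) == 0) stop("no requested atom type present in the table")
  means <- matrix(NA_real_, nrow(kdf), length(datasets),
                  dimnames = list(NULL, datasets))
  for (j in seq_along(datasets)) {
    sub <- tab[tab$dataset == datasets[j], ]
    means[, j] <- mapply(function(r, a)
      mean(sub$dloss_raw[sub$resname == r & sub$atom == a]),
      kdf$resname, kdf$atom)
  }
  keylab <- paste(kdf$resname, kdf$atom)
  ranks <- matrix(NA_integer_, nrow(kdf), length(datasets))
  for (j in seq_along(datasets)) {
    ord <- order(-means[, j], keylab)     # descending mean, lexicographic ties
    ranks[ord, j] <- seq_len(nrow(kdf)) - 1L
  }
  prod_rank <- apply(ranks, 1, prod)
  mean_rank <- rowMeans(ranks)
  ord <- order(prod_rank, mean_rank, keylab)
  overall <- integer(nrow(kdf))
  overall[ord] <- seq_len(nrow(kdf)) - 1L
  out <- cbind(kdf,
               stats::setNames(as.data.frame(means), paste0("mean_", datasets)),
               stats::setNames(as.data.frame(ranks), paste0("rank_", datasets)),
               rank_product = prod_rank, rank_overall = overall)
  attr(out, "absent") <- absent
  attr(out, "tie_policy") <- "mean per-dataset rank, then lexicographic key"
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' The statistic is the exact supremum over the pooled sample points of
#' the absolute difference of the two empirical CDFs (ties handled
#' exactly). The two-sided p-value uses the asymptotic Kolmogorov
#' distribution with the standard small-sample effective-n correction.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A \code{damage_test} list: statistic, p_value, n_a, n_b, method.
#' @export
ks_statistic <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  n_a <- length(sample_a)
  n_b <- length(sample_b)
  if (n_a == 0 || n_b == 0) stop("both samples must be non-empty")
  pts <- sort(unique(c(sample_a, sample_b)))
  ecdf_a <- vapply(pts, function(t) mean(sample_a <= t), 0)
  ecdf_b <- vapply(pts, function(t) mean(sample_b <= t), 0)
  d <- max(abs(ecdf_a - ecdf_b))
  ne <- n_a * n_b / (n_a + n_b)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  new_damage_test(d, min(max(p, 0), 1), n_a, n_b, "KS")
}

new_damage_test <- function(statistic, p_value, n_a, n_b, method) {
  t <- list(statistic = statistic, p_value = p_value, n_a = n_a, n_b = n_b,
            method = method)
  class(t) <- "damage_test"
  t
}

#' @export
print.damage_test <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, p = %.4g (n_a=%d, n_b=%d)\n",
              x$method, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Gaussian kernel density estimate of a damage signature
#'
#' Non-parametric estimate of the probability density underlying a
#' residue-type D_loss distribution. Gaussian kernels with Scott's-rule
#' bandwidth by default, evaluated on a regular grid spanning the data
#' plus three bandwidths on either side; the curve integrates to 1.
#'
#' @param sample Numeric vector with at least two distinct values.
#' @param bandwidth Kernel bandwidth; \code{NULL} for Scott's rule.
#' @param n Number of grid points (>= 256).
#' @return Data frame with columns \code{x} (abscissae) and \code{density};
#'   \code{attr(,"bandwidth")} records the bandwidth used.
#' @export
signature_kde <- function(sample, bandwidth = NULL, n = 512) {
  sample <- sample[is.finite(sample)]
  if (length(unique(sample)) < 2)
    stop("degenerate sample (all values equal): use a histogram instead")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd(sample)  # Scott's rule
  d <- stats::density(sample, bw = bandwidth, n = max(n, 256),
                      from = min(sample) - 3 * bandwidth,
                      to = max(sample) + 3 * bandwidth)
  out <- data.frame(x = d$x, density = d$y)
  attr(out, "bandwidth") <- bandwidth
  out
}

#' Two-sample Hotelling T-squared test
#'
#' Multivariate generalization of the two-sample t test: compares the mean
#' D_loss vectors (one coordinate per dose) of two groups of atoms using
#' the pooled covariance. The statistic is F-transformed and referred to
#' F(p, n_a + n_b - p - 1).
#'
#' @param group_a,group_b Numeric matrices, rows = group members, columns =
#'   doses (same columns in both).
#' @return A \code{damage_test} with the T-squared statistic and p-value.
#' @export
hotelling_t2 <- function(group_a, group_b) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  p <- ncol(group_a)
  if (ncol(group_b) != p) stop("groups must share the dose columns")
  n_a <- nrow(group_a)
  n_b <- nrow(group_b)
  if (n_a + n_b - 2 <= p)
    stop("too few members for ", p, " doses: need n_a + n_b - 2 > p")
  d <- colMeans(group_a) - colMeans(group_b)
  s <- ((n_a - 1) * stats::cov(group_a) + (n_b - 1) * stats::cov(group_b)) /
    (n_a + n_b - 2)
  si <- tryCatch(solve(s), error = function(e)
    stop("singular pooled covariance: consider dropping doses"))
  t2 <- (n_a * n_b / (n_a + n_b)) * drop(t(d) %*% si %*% d)
  f <- t2 * (n_a + n_b - p - 1) / (p * (n_a + n_b - 2))
  pv <- stats::pf(f, p, n_a + n_b - p - 1, lower.tail = FALSE)
  new_damage_test(t2, pv, n_a, n_b, "HotellingT2")
}

#' Coefficient of determination of an ordinary least-squares fit
#'
#' Fits y = a + b x by least squares and returns R^2 = 1 - SS_res/SS_tot.
#'
#' @param x,y Numeric vectors of equal length >= 3; x must not be constant.
#' @return A \code{damage_test} with statistic = R^2 (p-value from the
#'   slope's t test).
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length x and y with at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant: no regression possible")
  if (stats::sd(y) == 0) {
    warning("y is constant: R^2 defined as 0")
    return(new_damage_test(0, 1, length(x), length(y), "R2"))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # exact fits trip a benign warning
  r2 <- sm$r.squared
  pv <- sm$coefficients[2, 4]
  new_damage_test(r2, pv, length(x), length(y), "R2")
}

#' Damage-signature samples per residue type
#'
#' The damage signature of a residue type at a dose is the multiset of
#' C-alpha-normalized D_loss values over all heavy atoms of that type.
#'
#' @param tab A D_loss table.
#' @param resname Three-letter residue code.
#' @param dataset Dataset label; \code{NULL} pools all datasets.
#' @return Numeric vector of normalized D_loss values.
#' @export
damage_signature <- function(tab, resname, dataset = NULL) {
  sel <- tab$resname == resname
  if (!is.null(dataset)) sel <- sel & tab$dataset == dataset
  tab$dloss_ca_norm[sel]
}
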