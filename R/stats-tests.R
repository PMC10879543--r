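# Nonparametric statistics used by the pipeline: exact/approximate Wilcoxon
# tests (exact enumeration kept valid under ties via mid-ranks), a
# correlation matrix with Holm/BH multiplicity adjustment, Cohen's kappa for
# interrater agreement, and a cluster-level permutation test for group
# contrasts with repeated measures per dyad.

new_dyad_test <- function(statistic, p_value, n, method, alternative,
                          extra = list()) {
  structure(
    c(list(statistic = unname(statistic), p_value = unname(p_value), n = n,
           method = method, alternative = alternative), extra),
    class = "dyad_test")
}

#' @export
print.dyad_test <- function(x, ...) {
  cat(sprintf("<dyad_test> %s\n  statistic = %.4g, p = %.4g (%s, n = %s)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' @export
tidy.dyad_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         method = x$method, alternative = x$alternative)
}

#' @export
glance.dyad_test <- function(x, ...) tidy(x)

#' Wilcoxon signed-rank test
#'
#' Paired-sample signed-rank test. Zero differences are dropped; tied
#' absolute differences receive mid-ranks. For n (nonzero differences) up to
#' `exact_max` the null distribution of W+ is computed exactly by
#' enumerating sign assignments (a convolution over the mid-ranks, valid
#' under ties); beyond that a normal approximation with tie-corrected
#' variance and a 0.5 continuity correction is used.
#'
#' @param x,y Paired numeric vectors, or a single vector of differences in
#'   `x` with `y` omitted.
#' @param alternative "two.sided" (default), "greater" or "less" (refers to
#'   the location of x - y).
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default TRUE).
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return A `dyad_test` with the W+ statistic.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater", "less"),
                                 continuity = TRUE, exact_max = 25) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("All differences are zero; the signed-rank test is undefined.")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])

  if (n <= exact_max) {
    # Exact null of W+ via convolution over doubled mid-ranks (integers).
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1) # index i -> count of doubled-sum (i-1)
    dist[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(total + 1 - rk)])
      dist <- dist + shifted
    }
    probs <- dist / sum(dist)
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    cc <- if (continuity) 0.5 else 0
    if (sigma == 0) {
      p <- 1
    } else {
      z_g <- (w_plus - mu - cc) / sigma
      z_l <- (w_plus - mu + cc) / sigma
      p <- switch(alternative,
                  two.sided = min(1, 2 * min(pnorm(z_l), 1 - pnorm(z_g))),
                  greater = 1 - pnorm(z_g),
                  less = pnorm(z_l))
    }
    method <- "Wilcoxon signed-rank test (normal approximation, continuity-corrected)"
  }
  new_dyad_test(w_plus, p, n, method, alternative)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum (Mann-Whitney) test on the U statistic of `x`.
#' Exact enumeration of all rank arrangements when the smaller sample has at
#' most `exact_max` observations and there are no ties; otherwise a normal
#' approximation with tie-corrected variance and optional continuity
#' correction.
#'
#' @param x,y Numeric samples.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param continuity Continuity correction in the approximation (default
#'   TRUE).
#' @param exact_max Largest min(n) for exact enumeration (default 8).
#' @return A `dyad_test` with the U statistic of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              continuity = TRUE, exact_max = 8) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("Both samples must be non-empty.")
  all_r <- rank(c(x, y))
  u <- sum(all_r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0

  if (min(n1, n2) <= exact_max && !has_ties) {
    combs <- combn(n1 + n2, n1)
    stats_all <- colSums(matrix(all_r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(stats_all <= u + 1e-9)
    p_ge <- mean(stats_all >= u - 1e-9)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "Wilcoxon rank-sum test (exact)"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(all_r)
    sigma2 <- n1 * n2 / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    sigma <- sqrt(sigma2)
    cc <- if (continuity) 0.5 else 0
    if (sigma == 0) {
      p <- 1
    } else {
      z_g <- (u - mu - cc) / sigma
      z_l <- (u - mu + cc) / sigma
      p <- switch(alternative,
                  two.sided = min(1, 2 * min(pnorm(z_l), 1 - pnorm(z_g))),
                  greater = 1 - pnorm(z_g),
                  less = pnorm(z_l))
    }
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  new_dyad_test(u, p, c(n1, n2), method, alternative)
}

#' Correlation matrix with multiplicity adjustment
#'
#' Spearman or Pearson correlations over all column pairs of a numeric
#' table, with pairwise-complete handling of missing values and Holm or
#' Benjamini-Hochberg adjustment of the off-diagonal p-values. Spearman is
#' computed as the product-moment correlation of mid-ranks.
#'
#' @param table Data frame of numeric columns (one row per session or dyad).
#' @param method "spearman" (default) or "pearson".
#' @param adjust "holm" (default), "bh" or "none".
#' @param min_n Minimum complete pairs per correlation (default 3).
#' @return A `corr_matrix_result`: parameter names, `r`, raw and adjusted p
#'   matrices, and a character matrix `flag` marking undefined pairs
#'   (constant column or too few complete pairs).
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson"),
                               adjust = c("holm", "bh", "none"), min_n = 3) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  tab <- as.data.frame(table)
  tab <- tab[vapply(tab, is.numeric, logical(1))]
  p_names <- names(tab)
  k <- length(p_names)
  if (k < 2) abort("Need at least two numeric columns.")
  r <- matrix(NA_real_, k, k, dimnames = list(p_names, p_names))
  p <- r
  flag <- matrix("", k, k, dimnames = list(p_names, p_names))
  diag(r) <- 1
  diag(p) <- NA_real_
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- tab[[i]]; xj <- tab[[j]]
      ok <- complete.cases(xi, xj)
      if (sum(ok) < min_n) {
        flag[i, j] <- flag[j, i] <- "insufficient_n"
        next
      }
      if (sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
        flag[i, j] <- flag[j, i] <- "constant"
        next
      }
      ct <- suppressWarnings(
        cor.test(xi[ok], xj[ok], method = method, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  upper <- upper.tri(p)
  p_adj <- p
  adj_method <- switch(adjust, holm = "holm", bh = "BH", none = "none")
  p_adj[upper] <- p.adjust(p[upper], method = adj_method)
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(
    list(parameters = p_names, r = r, p_raw = p, p_adj = p_adj, flag = flag,
         method = method, adjust = adjust),
    class = "corr_matrix_result")
}

#' @export
print.corr_matrix_result <- function(x, ...) {
  cat(sprintf("<corr_matrix_result> %s correlations, %s-adjusted p (%d parameters)\n",
              x$method, x$adjust, length(x$parameters)))
  print(round(x$r, 3))
  invisible(x)
}

#' @export
tidy.corr_matrix_result <- function(x, ...) {
  k <- length(x$parameters)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    parameter1 = x$parameters[idx[, 1]],
    parameter2 = x$parameters[idx[, 2]],
    estimate = x$r[idx],
    p.value = x$p_raw[idx],
    p.adjusted = x$p_adj[idx],
    flag = x$flag[idx],
    method = x$method)
}

#' Heatmap of a correlation matrix result
#'
#' @param object A `corr_matrix_result`.
#' @param ... Unused.
#' @return A ggplot object; filled tiles are correlation coefficients,
#'   dots mark adjusted p < 0.05.
#' @export
autoplot.corr_matrix_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter1, .data$parameter2)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$estimate)) +
    ggplot2::geom_point(data = df[!is.na(df$p.adjusted) & df$p.adjusted < 0.05, ],
                        size = 2) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cohen's kappa interrater agreement
#'
#' Chance-corrected agreement between two equal-length label sequences:
#' kappa = (p_o - p_e) / (1 - p_e), with expected agreement p_e from the
#' product of marginal frequencies. Kappa is 0 at chance level and 1 at
#' perfect agreement.
#'
#' @param labels_a,labels_b Equal-length vectors of category labels.
#' @return The kappa value; `NA` with a warning when only one category is
#'   present in both raters (p_e = 1, kappa undefined).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b)) {
    abort("Label sequences must have equal length.")
  }
  cats <- union(labels_a, labels_b)
  ta <- factor(labels_a, levels = cats)
  tb <- factor(labels_b, levels = cats)
  tab <- table(ta, tb)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    warn("Only one shared category; kappa is undefined.")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Cluster-level permutation test for a group contrast
#'
#' Compares the mean of `metric` between two groups while respecting
#' clustering (repeated sessions of the same dyad): group labels are
#' permuted at the cluster level, so every observation of a dyad moves
#' together and pseudoreplication cannot inflate significance. The p-value
#' uses the add-one estimator p = (1 + #{|T*| >= |T|}) / (1 + n_perm).
#'
#' @param metric Numeric outcome, one value per observation.
#' @param group_labels Two-level group assignment per observation (constant
#'   within cluster).
#' @param cluster_ids Cluster (dyad) identifier per observation.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed (default 1).
#' @return A `dyad_test` with the observed mean difference (group 1 minus
#'   group 2, first level order of `factor(group_labels)`).
#' @export
permutation_group_compare <- function(metric, group_labels, cluster_ids,
                                      n_perm = 999, seed = 1) {
  metric <- as.numeric(metric)
  g <- factor(group_labels)
  if (nlevels(g) != 2) abort("group_labels must have exactly two levels.")
  cl <- as.character(cluster_ids)
  cl_tab <- distinct(tibble(cluster = cl, group = g))
  if (anyDuplicated(cl_tab$cluster)) {
    abort("Each cluster must belong to exactly one group.")
  }
  if (min(table(cl_tab$group)) < 2) abort("Need >= 2 clusters per group.")
  n_distinct_perms <- choose(nrow(cl_tab), sum(cl_tab$group == levels(g)[1]))
  if (n_distinct_perms < 20) {
    warn(sprintf("Only %d distinct cluster permutations; p-values are coarse.",
                 n_distinct_perms))
  }
  mean_diff <- function(groups_by_cluster) {
    gg <- groups_by_cluster[match(cl, cl_tab$cluster)]
    mean(metric[gg == levels(g)[1]]) - mean(metric[gg == levels(g)[2]])
  }
  t_obs <- mean_diff(cl_tab$group)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  t_null <- vapply(seq_len(n_perm), function(i) {
    mean_diff(sample(cl_tab$group))
  }, double(1))
  p <- (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  new_dyad_test(t_obs, p, length(metric),
                "Cluster-level permutation test of group mean difference",
                "two.sided",
                extra = list(n_perm = n_perm, seed = seed,
                             n_clusters = nrow(cl_tab)))
}

#' Model matrix export for mixed-model refitting
#'
#' Builds a tidy per-session model frame (outcome, fixed effects, and the
#' dyad/caregiver/infant grouping columns used as random effects) so any
#' external mixed-model tool can refit group contrasts; the package's own
#' inference uses [permutation_group_compare()].
#'
#' @param summaries Per-session summary tibble (parenting parameters joined
#'   with infant metrics).
#' @param meta Session metadata.
#' @param outcome Name of the outcome column.
#' @return Tibble with `outcome`, fixed-effect columns (`pnd`, `rearing`,
#'   `caregiver_role`) and grouping columns (`caregiver_id`, `infant_id`,
#'   `family_id`).
#' @export
attachment_model_matrix <- function(summaries, meta, outcome) {
  summaries <- as_tibble(summaries)
  stopifnot(outcome %in% names(summaries))
  summaries |>
    left_join(select(as_tibble(meta), "session_id", "pnd", "rearing",
                     "caregiver_role", "caregiver_id", "infant_id",
                     "family_id"),
              by = "session_id") |>
    mutate(outcome = .data[[outcome]]) |>
    select("session_id", "outcome", "pnd", "rearing", "caregiver_role",
           "caregiver_id", "infant_id", "family_id")
}
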