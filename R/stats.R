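#' Benjamini-Hochberg significance mask
#'
#' Step-up false-discovery-rate control: a p-value is declared significant
#' when its BH-adjusted value (via [stats::p.adjust()]) is at most `q`.
#'
#' @param pvals Numeric vector of p-values.
#' @param q Target FDR (default 0.05).
#' @return Logical mask, same length as `pvals`.
#' @examples
#' fdr_bh(c(0.001, 0.01, 0.02, 0.9), q = 0.05)
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH") <= q
}

#' Across-subject behavior correlation
#'
#' Pearson correlation (Spearman behind a flag) between a per-subject
#' information value and a behavioral score, with a two-sided p-value.
#'
#' @param values,scores Numeric vectors, one entry per subject (>= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble with `estimate`, `statistic`, `p.value`, `n`,
#'   `method`.
#' @export
behavior_correlation <- function(values, scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(values) != length(scores)) stop("lengths differ", call. = FALSE)
  if (length(values) < 3) stop("need at least 3 subjects", call. = FALSE)
  ct <- suppressWarnings(cor.test(values, scores, method = method))
  tibble(
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    p.value = ct$p.value,
    n = length(values),
    method = method
  )
}

# permutation p with the add-one rule; two-sided on |stat|
perm_p <- function(stat_obs, stat_null) {
  (1 + sum(abs(stat_null) >= abs(stat_obs))) / (length(stat_null) + 1)
}

# two-sided tail-probability matching: signed standard-normal quantile
t_to_z <- function(t_stat, p_two) {
  sign(t_stat) * qnorm(1 - pmin(p_two, 1) / 2)
}

#' Permutation group contrast of information maps
#'
#' Per node and term: a (paired) t statistic between two map sets with a
#' Monte-Carlo permutation p-value — sign-flipping of the paired differences,
#' or group-label shuffling when unpaired — converted to a signed z score by
#' two-sided tail matching, with an FDR mask across nodes and terms.
#'
#' @param maps_a,maps_b Tibbles with columns `subject`, `node`, `term` and a
#'   value column (`value` if present, else `main`). With `paired = TRUE`
#'   subjects must match across the two sets.
#' @param paired Paired design (default `TRUE`).
#' @param n_perm Number of permutations (default 5000; must be >= 2).
#' @param alpha Nominal level recorded with the result (default 0.05).
#' @param q FDR level for the significance mask (default 0.05).
#' @param rng_seed Optional seed for the permutation draws; with a seed the
#'   result is fully reproducible and the caller's RNG state is untouched.
#' @return A tibble of class `avp_contrast`: `node`, `term`, `t`, `p`, `z`,
#'   `significant`; attributes `alpha`, `n_perm`, `multiplicity = "BH"`.
#' @export
group_contrast <- function(maps_a, maps_b, paired = TRUE, n_perm = 5000,
                           alpha = 0.05, q = 0.05, rng_seed = NULL) {
  if (n_perm < 2) stop("`n_perm` must be >= 2 (degenerate permutation null)", call. = FALSE)
  va <- map_value_col(maps_a)
  vb <- map_value_col(maps_b)
  joined <- dplyr::inner_join(va, vb,
    by = c("subject", "node", "term"),
    suffix = c("_a", "_b")
  )
  if (nrow(joined) == 0) stop("no matching subject/node/term rows", call. = FALSE)
  run <- function() joined |>
    dplyr::group_by(.data$node, .data$term) |>
    dplyr::summarise(
      res = list(contrast_cell(.data$value_a, .data$value_b, paired, n_perm)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")
  out <- if (is.null(rng_seed)) run() else with_local_seed(rng_seed, run())
  out$z <- t_to_z(out$t, out$p)
  out$significant <- fdr_bh(out$p, q)
  structure(out,
    class = c("avp_contrast", class(out)),
    alpha = alpha, n_perm = n_perm, multiplicity = "BH"
  )
}

map_value_col <- function(maps) {
  col <- if ("value" %in% names(maps)) "value" else "main"
  tibble(
    subject = maps$subject, node = maps$node, term = maps$term,
    value = maps[[col]]
  )
}

contrast_cell <- function(a, b, paired, n_perm) {
  if (paired) {
    d <- a - b
    n <- length(d)
    t_obs <- mean(d) / (sd(d) / sqrt(n))
    flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
    dn <- d * flips
    t_null <- colMeans(dn) / (apply(dn, 2, sd) / sqrt(n))
  } else {
    x <- c(a, b)
    g <- rep(c(TRUE, FALSE), c(length(a), length(b)))
    t_stat <- function(lab) {
      xa <- x[lab]
      xb <- x[!lab]
      (mean(xa) - mean(xb)) /
        sqrt(var(xa) / length(xa) + var(xb) / length(xb))
    }
    t_obs <- t_stat(g)
    t_null <- vapply(seq_len(n_perm), function(i) t_stat(sample(g)), numeric(1))
  }
  list(t = t_obs, p = perm_p(t_obs, t_null))
}

#' Behavior regression with condition z-difference
#'
#' Per node and term: the t statistic of the regression of the information
#' value on the behavioral score across subjects, with a permutation p-value
#' obtained by shuffling the scores, converted to a signed z by two-sided
#' tail matching. When a second condition's maps are supplied, the z maps
#' are subtracted (`z_a - z_b`) and thresholded (default P < 0.005, the
#' conventional map threshold).
#'
#' @param maps_a Normalised maps of the condition of interest (must carry a
#'   `comprehension` column or `scores` must be given).
#' @param maps_b Optional second condition for the z-difference.
#' @param scores Optional tibble `subject`, `comprehension` overriding the
#'   maps' own scores.
#' @param n_perm Permutations (default 5000).
#' @param p_thresh Two-sided threshold on the (difference) z map
#'   (default 0.005).
#' @param rng_seed Optional seed for the permutation draws; the same seed is
#'   used for both conditions, so identical maps give an exactly zero
#'   z-difference.
#' @return A tibble of class `avp_contrast`: `node`, `term`, `t_a`, `p_a`,
#'   `z_a`, and with two conditions `t_b`, `p_b`, `z_b`, `z_difference`,
#'   `significant`.
#' @export
behavior_regression_z <- function(maps_a, maps_b = NULL, scores = NULL,
                                  n_perm = 5000, p_thresh = 0.005,
                                  rng_seed = NULL) {
  run_one <- function(maps) {
    if (is.null(rng_seed)) {
      regression_z_one(maps, scores, n_perm)
    } else {
      with_local_seed(rng_seed, regression_z_one(maps, scores, n_perm))
    }
  }
  ra <- run_one(maps_a)
  if (is.null(maps_b)) {
    out <- dplyr::rename(ra, t_a = "t", p_a = "p", z_a = "z")
    out$significant <- 2 * pnorm(-abs(out$z_a)) < p_thresh
  } else {
    rb <- run_one(maps_b)
    out <- dplyr::inner_join(ra, rb, by = c("node", "term"), suffix = c("_a", "_b"))
    out$z_difference <- out$z_a - out$z_b
    out$significant <- 2 * pnorm(-abs(out$z_difference)) < p_thresh
  }
  structure(out,
    class = c("avp_contrast", class(out)),
    n_perm = n_perm, threshold = p_thresh
  )
}

regression_z_one <- function(maps, scores, n_perm) {
  vals <- map_value_col(maps)
  if (is.null(scores)) {
    if (!"comprehension" %in% names(maps)) {
      stop("maps carry no `comprehension` column and no `scores` were given",
        call. = FALSE
      )
    }
    scores <- dplyr::distinct(
      tibble(subject = maps$subject, comprehension = maps$comprehension)
    )
  }
  vals <- dplyr::inner_join(vals, scores, by = "subject")
  vals |>
    dplyr::group_by(.data$node, .data$term) |>
    dplyr::summarise(
      res = list(regression_cell(.data$value, .data$comprehension, n_perm)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")
}

# slope t for value ~ score equals the correlation t; permutation by score
# shuffling
regression_cell <- function(values, scores, n_perm) {
  n <- length(values)
  if (n < 3) stop("need at least 3 subjects per cell", call. = FALSE)
  t_of_r <- function(r) r * sqrt((n - 2) / (1 - r^2))
  r_obs <- cor(values, scores)
  t_obs <- t_of_r(r_obs)
  perm <- matrix(0, nrow = n, ncol = n_perm)
  for (i in seq_len(n_perm)) perm[, i] <- sample(scores)
  r_null <- as.numeric(cor(values, perm))
  t_null <- t_of_r(pmin(pmax(r_null, -1 + 1e-12), 1 - 1e-12))
  p <- perm_p(t_obs, t_null)
  list(t = t_obs, p = p, z = t_to_z(t_obs, p))
}
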