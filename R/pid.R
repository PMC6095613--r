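#' Joint Gaussian model over (M, A, V) blocks
#'
#' The copula-standardised covariance (i.e. correlation) matrix over the
#' ordered variable blocks target `M`, predictor `A`, predictor `V`, which
#' fully describes the Gaussian-copula dependence the estimators use. In the
#' phase pipeline each block is 2-dimensional (real and imaginary unit-circle
#' coordinates), giving a 6x6 matrix; 1-dimensional blocks are supported for
#' the local (band-pass real signal) maps.
#'
#' @param m,a,v Numeric matrices (or vectors) with equal row counts: target
#'   and the two predictors.
#' @param copula Rank-normalise the columns first (default `TRUE`).
#' @return An object of class `avp_gauss_model` with fields `cov` (unit
#'   diagonal), `dims` (block dimensions), `n` (samples used).
#' @export
fit_joint_gauss <- function(m, a, v, copula = TRUE) {
  m <- as.matrix(m)
  a <- as.matrix(a)
  v <- as.matrix(v)
  n <- nrow(m)
  if (nrow(a) != n || nrow(v) != n) stop("blocks must share the sample count", call. = FALSE)
  if (n < 100) stop("need at least 100 samples to fit the joint model", call. = FALSE)
  if (copula) {
    m <- copula_normalise(m)
    a <- copula_normalise(a)
    v <- copula_normalise(v)
  }
  X <- cbind(m, a, v)
  X <- sweep(X, 2, colMeans(X))
  C <- stats::cov2cor(crossprod(X) / (n - 1))
  new_gauss_model(C, dims = c(ncol(m), ncol(a), ncol(v)), n = n)
}

#' @rdname fit_joint_gauss
#' @param cov Covariance matrix with unit diagonal, blocks ordered (M, A, V).
#' @param dims Integer vector of the three block dimensions.
#' @param n Number of samples the covariance was fitted from (informational).
#' @export
new_gauss_model <- function(cov, dims, n = NA_integer_) {
  cov <- as.matrix(cov)
  dims <- as.integer(dims)
  if (length(dims) != 3 || sum(dims) != nrow(cov)) {
    stop("`dims` must give three block sizes summing to nrow(cov)", call. = FALSE)
  }
  if (max(abs(cov - t(cov))) > 1e-8) stop("covariance must be symmetric", call. = FALSE)
  if (max(abs(diag(cov) - 1)) > 1e-6) {
    stop("covariance must have unit diagonal (copula-standardised inputs)", call. = FALSE)
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("covariance is not positive definite (smallest eigenvalue <= 1e-10)", call. = FALSE)
  }
  structure(list(cov = cov, dims = dims, n = as.integer(n)), class = "avp_gauss_model")
}

#' @export
print.avp_gauss_model <- function(x, ...) {
  cat(sprintf(
    "<avp_gauss_model: blocks M(%d) A(%d) V(%d), fitted on %s samples>\n",
    x$dims[1], x$dims[2], x$dims[3],
    ifelse(is.na(x$n), "?", format(x$n))
  ))
  invisible(x)
}

# index helpers for the three blocks
block_idx <- function(dims) {
  list(
    m = seq_len(dims[1]),
    a = dims[1] + seq_len(dims[2]),
    v = dims[1] + dims[2] + seq_len(dims[3])
  )
}

#' Analytic mutual information of a Gaussian model
#'
#' Closed-form MI (bits) between the target block and one or both predictor
#' blocks of an [fit_joint_gauss()] model: `-1/2 log2 det(C) / (det(C_M)
#' det(C_pred))` evaluated via Cholesky factors. Used for model-level
#' identities and oracles; no data, no bias correction.
#'
#' @param model An `avp_gauss_model`.
#' @param predictors `"a"`, `"v"`, or `"av"`.
#' @return MI in bits.
#' @export
gauss_block_mi <- function(model, predictors = c("a", "v", "av")) {
  predictors <- match.arg(predictors)
  ix <- block_idx(model$dims)
  pi_ <- switch(predictors, a = ix$a, v = ix$v, av = c(ix$a, ix$v))
  C <- model$cov
  hm <- chol_logdet_half(C[ix$m, ix$m, drop = FALSE])
  hp <- chol_logdet_half(C[pi_, pi_, drop = FALSE])
  hj <- chol_logdet_half(C[c(ix$m, pi_), c(ix$m, pi_), drop = FALSE])
  (hm + hp - hj) / log(2)
}

#' Interaction information from three mutual informations
#'
#' `I(M; A; V) = I(M; [A, V]) - I(M; A) - I(M; V)`. Negative values indicate
#' net redundancy (shared representation), positive values net synergy; it is
#' the difference synergy minus redundancy, so strong redundant and
#' synergistic structure can cancel in this net quantity.
#'
#' @param mi_a,mi_v,mi_av Mutual informations in bits.
#' @return Interaction information in bits.
#' @examples
#' interaction_information(0.3, 0.3, 0.4) # -0.2, net redundant
#' @export
interaction_information <- function(mi_a, mi_v, mi_av) {
  mi_av - mi_a - mi_v
}

#' Maximum-entropy trivariate surrogate
#'
#' The entropy-maximising joint Gaussian over (M, A, V) subject to preserving
#' the pairwise (M, A) and (M, V) distributions of the source model. In the
#' Gaussian family this has a closed form: the model in which A and V are
#' conditionally independent given M, i.e. the A-V cross block is replaced by
#' `S_AM S_MM^{-1} S_MV`. The result is invariant to the source's marginal
#' A-V dependence, which is what makes the redundancy measure comparable
#' across conditions with different stimulus correlation.
#'
#' @param model An `avp_gauss_model`.
#' @return An object of class `avp_maxent` with fields `cov_tilde`, `dims`,
#'   and `entropy_gain` (bits, always >= 0).
#' @export
maxent_surrogate <- function(model) {
  stopifnot(inherits(model, "avp_gauss_model"))
  ix <- block_idx(model$dims)
  C <- model$cov
  Smm <- C[ix$m, ix$m, drop = FALSE]
  Sam <- C[ix$a, ix$m, drop = FALSE]
  Smv <- C[ix$m, ix$v, drop = FALSE]
  cross <- Sam %*% solve(Smm, Smv) # A-V block under A _||_ V | M
  Ct <- C
  Ct[ix$a, ix$v] <- cross
  Ct[ix$v, ix$a] <- t(cross)
  ev <- eigen(Ct, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("max-ent covariance not positive definite", call. = FALSE)
  gain <- (chol_logdet_half(Ct) - chol_logdet_half(C)) / log(2)
  structure(
    list(cov_tilde = Ct, dims = model$dims, entropy_gain = gain),
    class = "avp_maxent"
  )
}

#' @export
print.avp_maxent <- function(x, ...) {
  cat(sprintf(
    "<avp_maxent: %dx%d, entropy gain %.4g bits>\n",
    nrow(x$cov_tilde), ncol(x$cov_tilde), x$entropy_gain
  ))
  invisible(x)
}

# log density of N(0, C) at rows of X, vectorised; log space throughout
logdens_gauss <- function(X, C) {
  d <- ncol(X)
  ch <- chol(C)
  z <- backsolve(ch, t(X), transpose = TRUE) # d x n
  -0.5 * (d * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# draw n samples from N(0, C)
rmvnorm_chol <- function(n, C) {
  Z <- matrix(rnorm(n * ncol(C)), nrow = n)
  Z %*% chol(C)
}

# pointwise Iccs machinery shared by iccs_redundancy() and local_pid_map():
# samples are drawn from the max-ent model; returns per-sample local terms.
iccs_local_terms <- function(model, maxent, n_mc, rng_seed) {
  ix <- block_idx(model$dims)
  C <- model$cov
  Ct <- maxent$cov_tilde
  X <- with_local_seed(rng_seed, rmvnorm_chol(n_mc, Ct))
  Xm <- X[, ix$m, drop = FALSE]
  Xa <- X[, ix$a, drop = FALSE]
  Xv <- X[, ix$v, drop = FALSE]
  l2 <- log(2)
  lp_m <- logdens_gauss(Xm, C[ix$m, ix$m, drop = FALSE])
  lp_a <- logdens_gauss(Xa, C[ix$a, ix$a, drop = FALSE])
  lp_v <- logdens_gauss(Xv, C[ix$v, ix$v, drop = FALSE])
  lp_ma <- logdens_gauss(cbind(Xm, Xa), C[c(ix$m, ix$a), c(ix$m, ix$a), drop = FALSE])
  lp_mv <- logdens_gauss(cbind(Xm, Xv), C[c(ix$m, ix$v), c(ix$m, ix$v), drop = FALSE])
  lq_av <- logdens_gauss(cbind(Xa, Xv), Ct[c(ix$a, ix$v), c(ix$a, ix$v), drop = FALSE])
  lq_mav <- logdens_gauss(X, Ct)
  i_ma <- (lp_ma - lp_m - lp_a) / l2
  i_mv <- (lp_mv - lp_m - lp_v) / l2
  i_mav <- (lq_mav - lp_m - lq_av) / l2 # local joint info under the max-ent surrogate
  cc <- i_ma + i_mv - i_mav
  keep <- sign(i_ma) == sign(i_mv) & sign(i_mv) == sign(i_mav) & sign(i_mav) == sign(cc)
  list(X = X, i_ma = i_ma, i_mv = i_mv, i_mav = i_mav, c = cc, included = keep)
}

#' Redundancy by pointwise common change in surprisal (Iccs)
#'
#' Monte-Carlo integral of the local co-information `c = i(m;a) + i(m;v) -
#' i(m;a,v)` over the maximum-entropy surrogate distribution, where the
#' pairwise local terms use the source model's densities and the joint local
#' term uses the surrogate's. A sample contributes only when all four local
#' quantities share the same sign — the configurations that unambiguously
#' reflect a common (redundant) change in surprisal; other samples contribute
#' zero. All densities are evaluated in log space. The estimate is not
#' guaranteed non-negative.
#'
#' @param model Source `avp_gauss_model`.
#' @param maxent Its [maxent_surrogate()].
#' @param n_mc Monte-Carlo sample count (default 1e5; minimum 10,000).
#' @param rng_seed Integer seed; identical inputs give identical output.
#' @return List with `red` (bits), `mc_se` (Monte-Carlo standard error),
#'   `n_mc`, `included` (fraction of samples passing the sign conditions).
#' @export
iccs_redundancy <- function(model, maxent = maxent_surrogate(model),
                            n_mc = 1e5, rng_seed = 1) {
  stopifnot(inherits(model, "avp_gauss_model"), inherits(maxent, "avp_maxent"))
  if (n_mc < 1e4) stop("`n_mc` must be at least 10,000", call. = FALSE)
  lt <- iccs_local_terms(model, maxent, n_mc, rng_seed)
  contrib <- ifelse(lt$included, lt$c, 0)
  list(
    red = mean(contrib),
    mc_se = sd(contrib) / sqrt(n_mc),
    n_mc = as.integer(n_mc),
    included = mean(lt$included)
  )
}

#' Partial information decomposition of two predictors about a target
#'
#' Fits the joint Gaussian-copula model over the target block `m` and
#' predictor blocks `a`, `v`; estimates the three mutual informations with
#' [mi_gg()]; estimates redundancy with [iccs_redundancy()]; and derives the
#' remaining PID terms from the defining identities: `uni_a = mi_a - red`,
#' `uni_v = mi_v - red`, `syn = mi_av - mi_a - mi_v + red`. The identities
#' (`red + uni_a = mi_a`, the four terms sum to `mi_av`, and `syn - red`
#' equals the interaction information) hold to machine precision by
#' construction. Terms may be negative.
#'
#' @param m Target block (matrix/vector of samples).
#' @param a,v Predictor blocks.
#' @param n_mc,rng_seed Monte-Carlo controls for the redundancy integral.
#' @param bias_correct Bias-correction setting shared by all MI terms.
#' @return An object of class `avp_pid`: fields `red`, `uni_a`, `uni_v`,
#'   `syn`, `mi_a`, `mi_v`, `mi_av` (bits), `mc_samples`, `mc_se`,
#'   `rng_seed`.
#' @export
pid_decompose <- function(m, a, v, n_mc = 1e5, rng_seed = 1, bias_correct = TRUE) {
  m <- as.matrix(m)
  a <- as.matrix(a)
  v <- as.matrix(v)
  mc <- copula_normalise(m)
  ac <- copula_normalise(a)
  vc <- copula_normalise(v)
  model <- fit_joint_gauss(mc, ac, vc, copula = FALSE)
  mi_a <- mi_gg(mc, ac, bias_correct = bias_correct, copula = FALSE)
  mi_v <- mi_gg(mc, vc, bias_correct = bias_correct, copula = FALSE)
  mi_av <- mi_gg(mc, cbind(ac, vc), bias_correct = bias_correct, copula = FALSE)
  red <- iccs_redundancy(model, n_mc = n_mc, rng_seed = rng_seed)
  pid_from_terms(red$red, mi_a, mi_v, mi_av, red$mc_se, n_mc, rng_seed)
}

pid_from_terms <- function(red, mi_a, mi_v, mi_av, mc_se, n_mc, rng_seed) {
  structure(
    list(
      red = red,
      uni_a = mi_a - red,
      uni_v = mi_v - red,
      syn = mi_av - mi_a - mi_v + red,
      mi_a = mi_a, mi_v = mi_v, mi_av = mi_av,
      mc_samples = as.integer(n_mc), mc_se = mc_se,
      rng_seed = rng_seed
    ),
    class = "avp_pid"
  )
}

#' @rdname pid_decompose
#' @param model A prefitted `avp_gauss_model` (model-level route; the MI
#'   terms are then the model's analytic Gaussian values).
#' @export
pid_decompose_model <- function(model, n_mc = 1e5, rng_seed = 1) {
  red <- iccs_redundancy(model, n_mc = n_mc, rng_seed = rng_seed)
  pid_from_terms(
    red$red,
    gauss_block_mi(model, "a"),
    gauss_block_mi(model, "v"),
    gauss_block_mi(model, "av"),
    red$mc_se, n_mc, rng_seed
  )
}

#' @export
print.avp_pid <- function(x, ...) {
  cat("<avp_pid> (bits)\n")
  cat(sprintf(
    "  red   %+.5f   uni_a %+.5f   uni_v %+.5f   syn %+.5f\n",
    x$red, x$uni_a, x$uni_v, x$syn
  ))
  cat(sprintf(
    "  mi_a  %+.5f   mi_v  %+.5f   mi_av %+.5f   (mc_se %.2g, n_mc %d)\n",
    x$mi_a, x$mi_v, x$mi_av, x$mc_se, x$mc_samples
  ))
  invisible(x)
}

#' PID of two neural regions about a stimulus target
#'
#' Role-swapped decomposition: the two predictor blocks are neural signals
#' and the target block is a unimodal speech signal, quantifying whether two
#' regions carry the same (redundant) or complementary (synergistic)
#' prediction of the stimulus.
#'
#' @param node1,node2 Predictor blocks (neural).
#' @param stimulus Target block (speech signal representation).
#' @inheritParams pid_decompose
#' @return An `avp_pid`; `mi_a`/`uni_a` refer to `node1`, `mi_v`/`uni_v` to
#'   `node2`.
#' @export
pid_regions_to_stimulus <- function(node1, node2, stimulus, n_mc = 1e5,
                                    rng_seed = 1, bias_correct = TRUE) {
  pid_decompose(stimulus, node1, node2,
    n_mc = n_mc, rng_seed = rng_seed,
    bias_correct = bias_correct
  )
}

#' Local probability-weighted information map
#'
#' Breaks the global information quantities into per-cell contributions over
#' a median split of the (copula-normalised, hence zero-median) 1-dimensional
#' variables: each cell is a sign combination of (m, a, v), and its value is
#' the Monte-Carlo mean of the local information restricted to that cell —
#' the probability-weighted local term `p*i`. Cell values sum to the
#' corresponding global quantity within Monte-Carlo error. Joint-MI
#' contributions are integrated under the source model; redundancy (Iccs)
#' contributions under the max-ent surrogate.
#'
#' @param model An `avp_gauss_model` with 1-dimensional blocks (band-pass
#'   real signals).
#' @param maxent Its [maxent_surrogate()].
#' @param n_mc,rng_seed Monte-Carlo controls.
#' @return A tibble of class `avp_local_map`: columns `m_bin`, `a_bin`,
#'   `v_bin` (`"low"`/`"high"`), `p_cell`, `pi_mi`, `pi_red`; attributes
#'   `mi_total`, `red_total`, `mc_se_mi`.
#' @export
local_pid_map <- function(model, maxent = maxent_surrogate(model),
                          n_mc = 1e5, rng_seed = 1) {
  stopifnot(inherits(model, "avp_gauss_model"))
  if (!all(model$dims == 1)) {
    stop("local maps are defined for 1-dimensional blocks (band-pass real signals)",
      call. = FALSE
    )
  }
  ix <- block_idx(model$dims)
  C <- model$cov

  # joint-MI contributions under the source model
  Xp <- with_local_seed(rng_seed, rmvnorm_chol(n_mc, C))
  lp_joint <- logdens_gauss(Xp, C)
  lp_m <- logdens_gauss(Xp[, ix$m, drop = FALSE], C[ix$m, ix$m, drop = FALSE])
  lp_av <- logdens_gauss(
    Xp[, c(ix$a, ix$v), drop = FALSE],
    C[c(ix$a, ix$v), c(ix$a, ix$v), drop = FALSE]
  )
  i_mi <- (lp_joint - lp_m - lp_av) / log(2)

  # redundancy contributions under the max-ent surrogate
  lt <- iccs_local_terms(model, maxent, n_mc, rng_seed + 1L)
  i_red <- ifelse(lt$included, lt$c, 0)

  bin_of <- function(X) {
    paste(
      ifelse(X[, 1] >= 0, "high", "low"),
      ifelse(X[, 2] >= 0, "high", "low"),
      ifelse(X[, 3] >= 0, "high", "low")
    )
  }
  lv <- c("low", "high")
  cells <- tidyr::expand_grid(m_bin = lv, a_bin = lv, v_bin = lv)
  key <- paste(cells$m_bin, cells$a_bin, cells$v_bin)

  cp <- factor(bin_of(Xp[, c(ix$m, ix$a, ix$v), drop = FALSE]), levels = key)
  cq <- factor(bin_of(lt$X[, c(ix$m, ix$a, ix$v), drop = FALSE]), levels = key)
  if (any(tabulate(cp, nbins = length(key)) == 0)) {
    warning("empty cell in local map; it contributes 0")
  }
  sum_by <- function(w, f) {
    s <- tapply(w, f, sum, default = 0)
    as.numeric(s[key]) / length(w)
  }
  out <- cells
  out$p_cell <- as.numeric(table(cp)[key]) / n_mc
  out$pi_mi <- sum_by(i_mi, cp)
  out$pi_red <- sum_by(i_red, cq)
  out <- as_tibble(out)
  structure(out,
    class = c("avp_local_map", class(out)),
    mi_total = mean(i_mi),
    red_total = mean(i_red),
    mc_se_mi = sd(i_mi) / sqrt(n_mc)
  )
}
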