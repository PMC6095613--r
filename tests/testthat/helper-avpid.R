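# shared fixtures, built in code

# quick config for signal-level tests (not a full cohort)
quick_config <- function(duration = 120, seed = 1, ...) {
  synth_config(n_subjects = 3, duration = duration, rng_seed = seed, ...)
}

# correlated bivariate Gaussian sample
rho_pair <- function(n, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  cbind(x, y)
}

# random correlation matrix with unit diagonal, comfortably positive definite
random_corr <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  stats::cov2cor(crossprod(A) + diag(d) * d)
}

# closed-form Gaussian MI in bits
gauss_mi_rho <- function(rho) -0.5 * log2(1 - rho^2)

# numerical oracle for the max-ent surrogate: maximise log det over the free
# A-V cross block with the (M,A) and (M,V) blocks pinned
maxent_numeric_oracle <- function(cov, dims) {
  ix <- list(
    m = seq_len(dims[1]),
    a = dims[1] + seq_len(dims[2]),
    v = dims[1] + dims[2] + seq_len(dims[3])
  )
  nfree <- dims[2] * dims[3]
  objective <- function(theta) {
    C <- cov
    C[ix$a, ix$v] <- matrix(theta, dims[2], dims[3])
    C[ix$v, ix$a] <- t(C[ix$a, ix$v, drop = FALSE])
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) return(1e6)
    -sum(log(ev))
  }
  start <- as.numeric(cov[ix$a, ix$v])
  fit <- optim(start, objective, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  C <- cov
  C[ix$a, ix$v] <- matrix(fit$par, dims[2], dims[3])
  C[ix$v, ix$a] <- t(C[ix$a, ix$v, drop = FALSE])
  C
}

# minimal PCM16 mono WAV writer (test oracle for the reader)
write_wav_pcm16 <- function(x, fs, path) {
  stopifnot(max(abs(x)) <= 1)
  samples <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(samples) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}
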