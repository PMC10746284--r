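# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Spearman correlation p-value: exact enumeration for n < 10 (ties handled
# through average ranks), t-approximation with n - 2 df otherwise.
spearman_p <- function(rho, rx, ry) {
  n <- length(rx)
  if (n < 10) {
    perms <- all_permutations(n)
    cross <- matrix(ry[perms], nrow(perms)) %*% rx
    sx <- stats::sd(rx)
    sy <- stats::sd(ry)
    if (sx == 0 || sy == 0) return(1)
    rhos <- (cross - n * mean(rx) * mean(ry)) / ((n - 1) * sx * sy)
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) return(0)
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
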