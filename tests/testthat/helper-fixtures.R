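# shared fixture builders (all data generated in code)

rand_spacers <- function(n, len = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- character(0L)
  while (length(out) < n)
    out <- unique(c(out, paste(
      sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
  out[seq_len(n)]
}

# a 4-guide library: geneA in SET1 and SET2, one safe-harbor, one
# non-targeting
tiny_library <- function(seed = 42L) {
  sp <- rand_spacers(4L, seed = seed)
  GuideLibrary(
    sgrna_id = c("geneA_SET1", "geneA_SET2", "SH_001", "NT_001"),
    spacer = sp,
    gene = c("geneA", "geneA", NA, NA),
    class = c("targeting", "targeting", "safe_harbor", "non_targeting"),
    subset = c("SET1", "SET2", "control", "control"))
}

write_library_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# NB counts for two groups with known per-sample scale, guide means and
# shared dispersion
nb_two_group <- function(n_guides, mu_a, mu_b, n_a = 2L, n_b = 2L,
                         alpha = 0.05, sf = NULL, seed = 1L) {
  set.seed(seed)
  m <- n_a + n_b
  if (is.null(sf)) sf <- rep(1, m)
  mu <- cbind(matrix(mu_a, n_guides, n_a), matrix(mu_b, n_guides, n_b))
  mu <- sweep(mu, 2L, sf, "*")
  k <- if (alpha > 0)
    matrix(rnbinom(n_guides * m, mu = mu, size = 1 / alpha), n_guides, m)
  else matrix(rpois(n_guides * m, mu), n_guides, m)
  dimnames(k) <- list(sprintf("g%03d", seq_len(n_guides)),
                      c(sprintf("A%d", seq_len(n_a)),
                        sprintf("B%d", seq_len(n_b))))
  k
}

# independent brute-force NB two-group GLM MLE: direct likelihood
# maximization over (b0, b1) by optim, with standard errors from the
# expected Fisher information assembled explicitly at the optimum;
# shares no code with the package's IRLS path
oracle_nb_fit <- function(y, sf, x, alpha) {
  nll <- function(b) {
    mu <- sf * exp(b[1] + b[2] * x)
    -sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  opt <- optim(c(log(mean(y / sf) + 0.1), 0), nll, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 500))
  mu <- sf * exp(opt$par[1] + opt$par[2] * x)
  X <- cbind(1, x)
  info <- t(X) %*% (X * (mu / (1 + alpha * mu)))
  se <- sqrt(diag(solve(info)))
  list(b0 = opt$par[1], b1 = opt$par[2], se1 = as.numeric(se[2]))
}
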