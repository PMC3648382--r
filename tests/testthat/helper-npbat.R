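# shared fixtures and small independent oracles, all built in code

# a case-control sample with genotypes at HWE and a case-only phenotype
make_case_control <- function(n_cases = 20, n_controls = 20, p = 0.3,
                              seed = 1, phenotype = TRUE) {
  set.seed(seed)
  n <- n_cases + n_controls
  status <- rep(c("case", "control"), c(n_cases, n_controls))
  y <- if (phenotype) c(rnorm(n_cases), rep(NA_real_, n_controls))
       else rep(NA_real_, n)
  list(
    samples = sample_table(status, phenotype = y),
    genotypes = coded_genotypes(rbinom(n, 2, p), marker_id = "sim")
  )
}

# all permutations of 1..n (recursive; fine for n <= 8)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

# random 2x3 case/control genotype table that is polymorphic on both margins
random_trend_table <- function() {
  repeat {
    N <- sample(40:2000, 1)
    gamma <- runif(1, 1 / 3, 3)
    R <- round(N * gamma / (1 + gamma))
    if (R < 1 || R > N - 1) next
    p <- runif(1, 0.1, 0.9)
    x <- rbinom(N, 2, p)
    status <- sample(rep(c("case", "control"), c(R, N - R)))
    n_k <- tabulate(factor(x, levels = 0:2), 3)
    r_k <- tabulate(factor(x[status == "case"], levels = 0:2), 3)
    D <- N * (n_k[2] + 4 * n_k[3]) - (n_k[2] + 2 * n_k[3])^2
    if (D > 0) {
      return(list(x = x, status = status, r = r_k, n = n_k, N = N,
                  R = R, gamma = R / (N - R)))
    }
  }
}
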