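# Expression-driven survival simulator shared by the survival and
# acceptance tests.
sim_surv_data <- function(n, betas, seed, censor_rate = 0.3,
                          G_extra = 0) {
  set.seed(seed)
  G <- length(betas) + G_extra
  ids <- sprintf("g%02d", seq_len(G))
  names(betas) <- ids[seq_along(betas)]
  z <- matrix(rnorm(G * n), G, n,
              dimnames = list(ids, sprintf("s%03d", 1:n)))
  expr <- 2^(3 + z) - 1  # so log2(x+1) recovers the latent gaussian
  x <- log2(expr[names(betas), , drop = FALSE] + 1)
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  lp <- drop(crossprod(x, betas))
  T_ <- rexp(n, rate = exp(lp) / 1000)
  if (censor_rate > 0) {
    C_ <- runif(n, 0, quantile(T_, 1 - censor_rate) * 2)
    time <- pmin(T_, C_); event <- as.integer(T_ <= C_)
  } else {
    time <- T_; event <- rep(1L, n)
  }
  list(expr = expr,
       surv = survival_table(colnames(expr), time, event),
       betas = betas)
}
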