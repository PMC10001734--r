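# Independent oracles used to cross-check the implementation: these are
# deliberately written with different algorithms (power iteration, truncated
# series, log-space products, explicit loops) than the package code paths.

# principal eigenvalue by power iteration on a positive matrix
power_iteration_lambda <- function(A, iter = 10000, tol = 1e-14) {
  v <- rep(1, nrow(A))
  lambda <- 0
  for (i in seq_len(iter)) {
    w <- A %*% v
    lambda_new <- max(abs(w))
    w <- w / lambda_new
    if (max(abs(w - v)) < tol) {
      v <- w
      lambda <- lambda_new
      break
    }
    v <- w
    lambda <- lambda_new
  }
  # Rayleigh quotient refinement
  as.numeric((t(v) %*% A %*% v) / (t(v) %*% v))
}

# truncated Neumann series sum_{k=1}^{kmax} N^k
neumann_series <- function(N, kmax = 200) {
  acc <- matrix(0, nrow(N), ncol(N))
  term <- diag(nrow(N))
  for (k in seq_len(kmax)) {
    term <- term %*% N
    acc <- acc + term
  }
  acc
}

# IFWA evaluated in log space
ifwa_log <- function(mu, nu, w) {
  c(mu = 1 - exp(sum(w * log1p(-mu))),
    nu = if (any(nu == 0 & w > 0)) 0 else exp(sum(w * log(nu))))
}

# random valid IFNs: draw (mu, nu) uniformly on the simplex mu + nu <= 1
random_ifns <- function(n) {
  a <- stats::runif(n)
  b <- stats::runif(n)
  mu <- pmin(a, b)
  nu <- 1 - pmax(a, b)
  tibble::tibble(mu = mu, nu = nu)
}

# random weights on the simplex
random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# a complete random long-format judgment set for n elements and k experts
random_judgments <- function(k, elements) {
  n <- length(elements)
  purrr::map(seq_len(k), function(e) {
    ifn <- random_ifns(n * n)
    grid <- expand.grid(row = elements, col = elements,
                        stringsAsFactors = FALSE)
    tibble::tibble(expert = sprintf("E%d", e), row = grid$row,
                   col = grid$col, mu = ifn$mu, nu = ifn$nu)
  }) |> purrr::list_rbind()
}

# the human-talent aggregated direct-relation matrix at full precision:
# cell sums over the six experts' crisp scores (values in
# {0, 0.4, 1.5, 2.1, 3.1, 3.6}) divided by 6; printed cells are these
# values rounded to 3 decimals
human_talent_Z_exact <- function() {
  num <- matrix(c(
    0.0, 18.1, 17.1, 17.6,
    19.1, 0.0, 20.1, 16.6,
    16.1, 17.0, 0.0, 17.1,
    17.1, 17.1, 17.5, 0.0
  ), 4, 4, byrow = TRUE,
  dimnames = list(c("SH19", "SH20", "SH21", "SH22"),
                  c("SH19", "SH20", "SH21", "SH22")))
  num / 6
}
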