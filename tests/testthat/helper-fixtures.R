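# Shared fixtures and independent oracles, all built in code.

# Small hand-buildable cohort data frame.
make_records <- function(n = 10, seed = 1, group = "NAFLD") {
  set.seed(seed)
  data.frame(id = sprintf("p%02d", seq_len(n)), group = group,
             ac = runif(n, 0.5, 1.2), bscd = runif(n, 60, 117),
             ls = runif(n, 3, 20), pdff = runif(n, 0, 45),
             bmi = runif(n, 19, 45),
             stringsAsFactors = FALSE)
}

make_cohort <- function(n = 10, seed = 1, group = "NAFLD") {
  cohort(make_records(n, seed, group), label = group, provenance = "fixture")
}

# Default generator link truth (the package fixture values).
AC_LINK_TRUTH <- c(5.447, 1.974, -15.93)

# Brute-force AUC: explicit concordant / tied pair enumeration.
auc_pair_counting <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Brute-force Youden maximiser over the same candidate set, written
# independently (explicit confusion tables, loop form).
youden_brute_force <- function(scores, labels) {
  lab <- as.logical(labels)
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  best_j <- -Inf
  best_cut <- NA_real_
  for (cut in cand) {
    tp <- sum(scores >= cut & lab)
    fp <- sum(scores >= cut & !lab)
    j <- tp / sum(lab) - fp / sum(!lab)
    if (j > best_j + 1e-12 || (abs(j - best_j) <= 1e-12 && cut > best_cut)) {
      best_j <- j
      best_cut <- cut
    }
  }
  list(cutoff = best_cut, j = best_j)
}

# Grid + polish oracle for the 3-parameter exponential SSE minimum.
nls_grid_polish_sse <- function(x, y, b1_range, b2_range, b3_range,
                                steps = 8) {
  sse <- function(b) sum((y - (b[1] * exp(b[2] * x) + b[3]))^2)
  grid <- expand.grid(b1 = seq(b1_range[1], b1_range[2], length.out = steps),
                      b2 = seq(b2_range[1], b2_range[2], length.out = steps),
                      b3 = seq(b3_range[1], b3_range[2], length.out = steps))
  vals <- apply(grid, 1, sse)
  best <- min(vapply(order(vals)[1:5], function(i) {
    p <- optim(as.numeric(grid[i, ]), sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    optim(p$par, sse, method = "BFGS",
          control = list(maxit = 1000, reltol = 1e-14))$value
  }, numeric(1)))
  best
}
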