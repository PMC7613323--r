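# Independent oracles, deliberately coded apart from the package's
# production paths: dense-covariance likelihoods, a Cox-de Boor recursion,
# grid searches, and a literal step-up procedure.

# dense multivariate normal log-density via solve()/determinant()
dense_mvn_logdens <- function(y, mu, V) {
  r <- y - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (length(y) * log(2 * pi) + ld + drop(crossprod(r, solve(V, r))))
}

# brute-force mixture log-likelihood building each subject's dense
# compound-symmetry covariance explicitly
oracle_dense_loglik <- function(cohort, spec, params) {
  ids <- unique(cohort$subject_id)
  total <- 0
  for (id in ids) {
    rows <- cohort[cohort$subject_id == id, , drop = FALSE]
    X <- design_matrix(rows$ga_weeks, spec)
    n <- nrow(rows)
    V <- params$sigma_b^2 * matrix(1, n, n) + params$sigma_e^2 * diag(n)
    dens <- vapply(seq_len(params$G), function(g)
      dense_mvn_logdens(rows$z, drop(X %*% params$beta[, g]), V), numeric(1))
    total <- total + log(sum(params$pi * exp(dens - max(dens)))) + max(dens)
  }
  total
}

# Bayes-rule posteriors from the dense densities
oracle_dense_posteriors <- function(cohort, spec, params) {
  ids <- unique(cohort$subject_id)
  P <- matrix(0, length(ids), params$G)
  for (i in seq_along(ids)) {
    rows <- cohort[cohort$subject_id == ids[i], , drop = FALSE]
    X <- design_matrix(rows$ga_weeks, spec)
    n <- nrow(rows)
    V <- params$sigma_b^2 * matrix(1, n, n) + params$sigma_e^2 * diag(n)
    dens <- vapply(seq_len(params$G), function(g)
      dense_mvn_logdens(rows$z, drop(X %*% params$beta[, g]), V), numeric(1))
    w <- params$pi * exp(dens - max(dens))
    P[i, ] <- w / sum(w)
  }
  P
}

# Cox-de Boor recursion for a single B-spline basis function; the closed
# half-open convention is extended so the right boundary takes its left limit
cox_de_boor <- function(x, knots, j, d) {
  if (d == 0) {
    last <- max(knots)
    return(as.numeric((x >= knots[j] & x < knots[j + 1]) |
                        (x == last & knots[j] < last &
                           knots[j + 1] == last)))
  }
  a <- 0
  if (knots[j + d] > knots[j])
    a <- (x - knots[j]) / (knots[j + d] - knots[j]) *
      cox_de_boor(x, knots, j, d - 1)
  b <- 0
  if (knots[j + d + 1] > knots[j + 1])
    b <- (knots[j + d + 1] - x) / (knots[j + d + 1] - knots[j + 1]) *
      cox_de_boor(x, knots, j + 1, d - 1)
  a + b
}

oracle_bspline_row <- function(x, spec) {
  kn <- c(rep(spec$boundary_knots[1], spec$degree + 1), spec$internal_knots,
          rep(spec$boundary_knots[2], spec$degree + 1))
  vapply(seq_len(spec$p), function(j) cox_de_boor(x, kn, j, spec$degree),
         numeric(1))
}

# profile-likelihood grid oracle for the single-class linear mixed model:
# GLS beta at each (sigma_b, sigma_e), dense evaluation, iterative grid
# refinement
oracle_lmm_profile <- function(cohort, spec, rounds = 5, width = c(1, 1)) {
  ids <- unique(cohort$subject_id)
  blocks <- lapply(ids, function(id) {
    rows <- cohort[cohort$subject_id == id, , drop = FALSE]
    list(y = rows$z, X = design_matrix(rows$ga_weeks, spec))
  })
  eval_profile <- function(sb, se) {
    p <- ncol(blocks[[1]]$X)
    A <- matrix(0, p, p); bv <- numeric(p)
    for (bl in blocks) {
      n <- length(bl$y)
      Vi <- solve(sb^2 * matrix(1, n, n) + se^2 * diag(n))
      A <- A + crossprod(bl$X, Vi %*% bl$X)
      bv <- bv + crossprod(bl$X, Vi %*% bl$y)
    }
    beta <- solve(A, bv)
    ll <- 0
    for (bl in blocks) {
      n <- length(bl$y)
      V <- sb^2 * matrix(1, n, n) + se^2 * diag(n)
      ll <- ll + dense_mvn_logdens(bl$y, drop(bl$X %*% beta), V)
    }
    ll
  }
  ctr <- c(0.5, 0.5); w <- width
  best <- c(NA, NA, -Inf)
  for (r in seq_len(rounds)) {
    sbs <- seq(max(ctr[1] - w[1], 1e-4), ctr[1] + w[1], length.out = 13)
    ses <- seq(max(ctr[2] - w[2], 1e-3), ctr[2] + w[2], length.out = 13)
    for (sb in sbs) for (se in ses) {
      ll <- eval_profile(sb, se)
      if (ll > best[3]) best <- c(sb, se, ll)
    }
    ctr <- best[1:2]
    w <- w / 5
  }
  list(sigma_b = best[1], sigma_e = best[2], loglik = best[3])
}

# independently coded EM for a finite mixture of regressions with a shared
# residual variance (one observation per subject)
oracle_mixreg_em <- function(y, X, G, n_restarts = 5, seed = 1,
                             max_iter = 2000, tol = 1e-10) {
  n <- length(y); p <- ncol(X)
  best_ll <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed * 1000 + r)
    grp <- sample.int(G, n, replace = TRUE)
    pi_g <- rep(1 / G, G)
    beta <- sapply(seq_len(G), function(g) {
      sel <- grp == g
      qr.solve(X[sel, , drop = FALSE] +
                 matrix(rnorm(sum(sel) * p, 0, 1e-6), sum(sel)), y[sel])
    })
    s2 <- var(y)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      D <- sapply(seq_len(G), function(g)
        dnorm(y, drop(X %*% beta[, g]), sqrt(s2), log = TRUE))
      A <- sweep(D, 2, log(pi_g), "+")
      mx <- apply(A, 1, max)
      ll <- sum(mx + log(rowSums(exp(A - mx))))
      P <- exp(A - mx - log(rowSums(exp(A - mx))))
      if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
      ll_old <- ll
      pi_g <- colMeans(P)
      for (g in seq_len(G)) {
        w <- P[, g]
        beta[, g] <- solve(crossprod(X * w, X) + diag(1e-10, p),
                           crossprod(X, w * y))
      }
      s2 <- sum(P * (y - X %*% beta)^2) / n
    }
    if (ll > best_ll) best_ll <- ll
  }
  best_ll
}

# brute-force partial-likelihood grid search for a single Cox coefficient,
# distinct event times (Breslow = Efron with no ties)
oracle_cox_grid <- function(time, status, x, rounds = 6) {
  pl <- function(b) {
    ll <- 0
    for (i in which(status == 1)) {
      risk <- time >= time[i]
      ll <- ll + x[i] * b - log(sum(exp(x[risk] * b)))
    }
    ll
  }
  ctr <- 0; w <- 5
  for (r in seq_len(rounds)) {
    grid <- seq(ctr - w, ctr + w, length.out = 41)
    vals <- vapply(grid, pl, numeric(1))
    ctr <- grid[which.max(vals)]
    w <- w / 10
  }
  ctr
}

# literal Benjamini-Hochberg step-up: check every candidate cutoff
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# random small mixture instance for oracle-equivalence checks
random_instance <- function(seed) {
  set.seed(seed)
  n_subj <- sample(2:5, 1)
  G <- sample(1:3, 1)
  spec <- spline_spec(internal_knots = runif(1, 20, 30),
                      boundary_knots = c(14, 37))
  rows <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    n_i <- sample(1:4, 1)
    data.frame(subject_id = sprintf("S%02d", i),
               ga_weeks = sort(runif(n_i, 14, 37)),
               z = rnorm(n_i))
  }))
  pi_g <- runif(G); pi_g <- pi_g / sum(pi_g)
  params <- lcmm_params(pi_g, matrix(rnorm(spec$p * G), spec$p, G),
                        sigma_b = runif(1, 0, 1),
                        sigma_e = runif(1, 0.2, 1.5))
  list(cohort = rows, spec = spec, params = params)
}
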