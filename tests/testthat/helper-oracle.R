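# Independent oracles used across the suite. These are written against the
# definitions, not against the package internals, and stay deliberately
# naive/slow.

# Brute-force elementary-mode enumeration by support subsets: a flux vector v
# with support R is elementary iff the nullspace of S restricted to R is
# one-dimensional with a basis vector that is nonzero everywhere on R and can
# be signed to satisfy irreversibility. Support-minimality is then enforced
# across all candidates.
brute_force_modes <- function(network, tol = 1e-9) {
  S <- stoichiometric_matrix(network)
  rev <- network$reactions$reversible
  q <- ncol(S)
  cands <- list()
  for (mask in 1:(2^q - 1)) {
    supp <- which(bitwAnd(mask, 2^(seq_len(q) - 1)) > 0)
    Ssub <- S[, supp, drop = FALSE]
    ns <- .null_space(Ssub, tol)
    if (ncol(ns) != 1L) next
    v <- ns[, 1]
    if (any(abs(v) < tol)) next          # support must be exactly supp
    full <- numeric(q); full[supp] <- v
    ok_pos <- all(full[!rev] >= -tol)
    ok_neg <- all(-full[!rev] >= -tol)
    if (!ok_pos && !ok_neg) next
    if (!ok_pos) full <- -full
    if (ok_pos && ok_neg) {
      # fully reversible support: canonical sign, first nonzero positive
      if (full[supp[1]] < 0) full <- -full
    }
    cands[[length(cands) + 1L]] <- full / max(abs(full))
  }
  if (!length(cands)) return(matrix(0, 0, q, dimnames = list(NULL,
                                                             colnames(S))))
  V <- do.call(rbind, cands)
  supp <- abs(V) > tol
  keep <- vapply(seq_len(nrow(V)), function(i) {
    !any(vapply(seq_len(nrow(V)), function(j)
      j != i && all(supp[j, ] <= supp[i, ]) && sum(supp[j, ]) < sum(supp[i, ]),
      NA))
  }, NA)
  V <- V[keep, , drop = FALSE]
  colnames(V) <- colnames(S)
  V
}

.null_space <- function(A, tol = 1e-9) {
  if (ncol(A) == 0L) return(matrix(0, 0, 0))
  sv <- svd(A, nu = 0, nv = ncol(A))
  d <- c(sv$d, rep(0, ncol(A) - length(sv$d)))
  sv$v[, d < tol * max(d, 1), drop = FALSE]
}

# Canonical comparable form of a mode matrix: each row scaled to max |.| = 1
# with canonical sign, rows sorted by support key.
canonical_modes <- function(V, tol = 1e-7) {
  if (nrow(V) == 0L) return(V)
  V <- t(apply(V, 1, function(v) {
    v <- v / max(abs(v))
    if (v[which(abs(v) > tol)[1]] < 0) v <- -v
    round(v, 9)
  }))
  V[order(apply(V, 1, paste, collapse = ",")), , drop = FALSE]
}

expect_same_modes <- function(a, b, tol = 1e-6) {
  ca <- canonical_modes(a); cb <- canonical_modes(b)
  expect_equal(dim(ca), dim(cb))
  if (nrow(ca)) expect_lt(max(abs(ca - cb)), tol)
}

# Random small network with guaranteed uptake/excretion structure: a core of
# random internal conversions plus exchange reactions, so nontrivial modes
# exist with positive probability.
random_toy_network <- function(n_internal = 3, n_core = 4, seed = 1) {
  set.seed(seed)
  mets <- paste0("m", seq_len(n_internal))
  lines <- c("up: s.Ext => m1",
             paste0("out: m", n_internal, " => p.Ext"))
  for (k in seq_len(n_core)) {
    from <- sample(mets, 1)
    to <- sample(setdiff(mets, from), 1)
    coeff <- sample(1:2, 2, replace = TRUE)
    arrow <- if (stats::runif(1) < 0.3) "<=>" else "=>"
    lines <- c(lines, paste0("r", k, ": ", coeff[1], " ", from, " ", arrow,
                             " ", coeff[2], " ", to))
  }
  suppressMessages(parse_reaction_list(lines))
}

# Independent evaluation of Alberty-style transformed group potentials,
# written as an explicit binding-polynomial computation relative to the
# least-protonated species (a different algebraic route than the package's
# log-sum-exp over species potentials).
oracle_group_potential <- function(species, T, pH, I, conc = 1) {
  RT <- 8.314e-3 * T
  alberty_A <- 1.10708 - 1.54508e-3 * T + 5.95584e-6 * T^2
  mu <- numeric(nrow(species))
  for (i in seq_len(nrow(species))) {
    dh_term <- alberty_A * (species$z[i]^2 - species$nH[i]) *
      sqrt(I) / (1 + 1.6 * sqrt(I))
    mu[i] <- species$dfG0[i] + species$nH[i] * RT * log(10) * pH - dh_term +
      RT * log(conc)
  }
  ref <- which.min(species$nH)
  P <- sum(exp(-(mu - mu[ref]) / RT))   # binding polynomial
  list(mu = mu[ref] - RT * log(P),
       weights = exp(-(mu - mu[ref]) / RT) / P)
}

# Coarse-to-fine grid search for the b that matches a target expectation.
grid_search_b <- function(x, xi_hat, target, n_grid = 4000) {
  grid <- exp(seq(log(1e-4), log(1e4), length.out = n_grid))
  m <- vapply(grid, function(b)
    sum(boltzmann_probabilities(x, xi_hat, b)$p * x), 0)
  grid[which.min(abs(m - target))]
}
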