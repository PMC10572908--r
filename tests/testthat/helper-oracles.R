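# Independent oracles and generators used across the suite. These never
# call the code paths they check.

# Exact constrained optimum for shared-property-center surrogate
# landscapes: minimize the summed energy quadratic subject to
# (c - c_sigma)' Qbar (c - c_sigma) <= epsilon, Qbar the mean property
# curvature. This is the classical trust-region subproblem; after
# whitening the constraint it is solved through the secular equation for
# the Lagrange multiplier (root-found to 1e-14), so the reference energy
# is exact to numerical precision in any dimension.
surrogate_constrained_optimum <- function(spec, epsilon = 0.01) {
  d <- spec$dim
  mols <- spec$molecules
  c_sigma <- mols[[1]]$c_sigma
  Qbar <- Reduce(`+`, lapply(mols, `[[`, "Q_sigma")) / length(mols)
  H <- Reduce(`+`, lapply(mols, `[[`, "Q_e"))
  rhs <- Reduce(`+`, lapply(mols, function(m) m$Q_e %*% m$c_e))
  c_star <- drop(solve(H, rhs))
  e_at <- function(cc) sum(vapply(mols, function(m) {
    de <- cc - m$c_e
    m$e_star + drop(crossprod(de, m$Q_e %*% de))
  }, numeric(1)))
  dev_at <- function(cc) {
    ds <- cc - c_sigma
    drop(crossprod(ds, Qbar %*% ds))
  }
  if (dev_at(c_star) <= epsilon) {
    return(list(c = c_star, energy = e_at(c_star), boundary = FALSE))
  }
  L <- t(chol(Qbar))          # Qbar = L L'
  B <- t(solve(L))            # c = c_sigma + B z with ||z||^2 <= epsilon
  dvec <- c_sigma - c_star
  At <- t(B) %*% H %*% B
  bt <- drop(t(B) %*% H %*% dvec)
  r <- sqrt(epsilon)
  znorm <- function(lam) sqrt(sum(solve(At + diag(lam, d), bt)^2))
  hi <- 1
  while (znorm(hi) > r) hi <- hi * 2
  lam <- stats::uniroot(function(l) znorm(l) - r, c(0, hi), tol = 1e-14)$root
  z <- -solve(At + diag(lam, d), bt)
  c_opt <- drop(c_sigma + B %*% z)
  list(c = c_opt, energy = e_at(c_opt), boundary = TRUE)
}

# Random valid segmented basis library for round-trip property tests.
# Every primitive participates in at least one contracted function (rows
# of zeros would not survive the per-function export of the gaussian
# dialect).
random_basis_library <- function(seed) {
  withr::with_seed(seed, {
    elements <- sample(c("H", "C", "N", "O", "S"), sample(2:4, 1))
    entries <- lapply(elements, function(el) {
      n_shells <- sample(1:3, 1)
      shells <- lapply(seq_len(n_shells) - 1L, function(l) {
        np <- sample((l + 1):6, 1)
        nc <- sample(1:np, 1)
        z <- sort(exp(stats::rnorm(np, 1, 1.5)), decreasing = TRUE)
        while (any(diff(z) >= 0)) z <- sort(z * stats::runif(np, 0.9, 1.1),
                                            decreasing = TRUE)
        cf <- matrix(0, np, nc)
        # segmented-ish: chop primitives into nc consecutive groups
        breaks <- sort(sample(seq_len(np - 1), nc - 1))
        groups <- findInterval(seq_len(np), c(0, breaks) + 1)
        for (i in seq_len(np)) cf[i, groups[i]] <- stats::rnorm(1, 0.5, 0.3)
        cf[cf == 0 & row(cf) == col(cf)] <- cf[cf == 0 & row(cf) == col(cf)]
        # guarantee nonzero entries
        cf[cbind(seq_len(np), groups)] <-
          ifelse(cf[cbind(seq_len(np), groups)] == 0, 0.1,
                 cf[cbind(seq_len(np), groups)])
        basis_shell(l, z, cf)
      })
      element_basis(el, shells)
    })
    basis_set_library(paste0("random-", seed), entries)
  })
}

# Fixed-response backend: returns preset shieldings per molecule name and
# a constant energy; used to check the error-metric plumbing without any
# landscape.
fixed_backend <- function(sigma_by_mol, energy = -1) {
  qc_backend_function(function(mol, per_atom, functional, nuclei) {
    s <- sigma_by_mol[[mol$name]]
    list(sigma = stats::setNames(s[seq_along(nuclei)], nuclei),
         energy = energy)
  }, name = "fixed", cache = FALSE)
}
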