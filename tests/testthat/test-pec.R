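# The PEC Monte-Carlo optimizer over surrogate landscapes.

test_that("objective_delta is the mean absolute deviation from the targets", {
  m <- fixture_molecules()$methane
  be <- fixed_backend(list(methane = c(1, 2, 3)))
  lib <- pecs_synthetic(1)
  prob <- pec_problem(
    fitting = list(list(molecule = m, nuclei = 2:4)),
    variable = list(element = "C", l = 1L),
    library = lib,
    sigma_ideal = c(0, 0, 0)
  )
  start <- pecnmr:::variable_shell(prob$library, prob$variable)$coefficients
  expect_equal(objective_delta(start, prob, be), 2)
  prob$sigma_ideal <- c(1, 2, 3)
  expect_identical(objective_delta(start, prob, be), 0)
})

test_that("surrogate targets equal the landscape's base values", {
  spec <- make_surrogate(seed = 4, dim = 2)
  prob <- surrogate_problem(spec)
  be <- qc_backend_surrogate(spec)
  targets <- compute_ideal_targets(prob, be)
  expect_identical(unname(targets), c(108.06, 50.87, 192.94))
  # objective vanishes at the shared property center
  expect_identical(objective_delta(spec$molecules[[1]]$c_sigma, prob, be), 0)
})

test_that("the constrained optimum matches the exact oracle within energy_tol", {
  for (case in list(c(seed = 1, dim = 1), c(seed = 42, dim = 2),
                    c(seed = 3, dim = 3))) {
    spec <- make_surrogate(seed = case[["seed"]], dim = case[["dim"]])
    prob <- surrogate_problem(spec)
    be <- qc_backend_surrogate(spec)
    cfg <- pec_config(seed = 7, renormalize = FALSE, n_samples = 1000L,
                      max_rounds = 40L)
    res <- pec_optimize(prob, cfg, be)
    orc <- surrogate_constrained_optimum(spec, cfg$diapason)
    expect_true(res$feasible)
    expect_lte(res$delta_bar, cfg$diapason)
    expect_lt(abs(res$total_energy - orc$energy), cfg$energy_tol)
  }
})

test_that("a feasible start at the energy minimum is returned unchanged", {
  # hand-built landscape whose energy centers coincide with the property
  # center: the start at that point is feasible and already optimal
  dim <- 2L
  c0 <- c(0.3, -0.1)
  land <- function(sigma_star, e_star) {
    list(sigma_star = sigma_star, c_sigma = c0, Q_sigma = diag(dim),
         e_star = e_star, c_e = c0, Q_e = diag(dim), nucleus = 1L)
  }
  spec <- structure(
    list(dim = dim, seed = 0L, variable = list(element = "C", l = 1L),
         molecules = list(acetylene = land(108.06, -77.33),
                          ethylene = land(50.87, -78.59),
                          methane = land(192.94, -40.52))),
    class = "surrogate_spec"
  )
  prob <- surrogate_problem(spec, start = c0)
  res <- pec_optimize(prob, pec_config(seed = 3, renormalize = FALSE),
                      qc_backend_surrogate(spec))
  expect_true(res$feasible)
  expect_identical(drop(res$best_coefficients), c0)
  expect_identical(res$delta_bar, 0)
})

test_that("fixed seeds reproduce the full result", {
  spec <- make_surrogate(seed = 11, dim = 2)
  prob <- surrogate_problem(spec)
  be <- qc_backend_surrogate(spec)
  cfg <- pec_config(seed = 21, renormalize = FALSE, n_samples = 200L)
  r1 <- pec_optimize(prob, cfg, be)
  r2 <- pec_optimize(prob, cfg, be)
  expect_identical(r1$best_coefficients, r2$best_coefficients)
  expect_identical(r1$trace, r2$trace)
})

test_that("the incumbent's energy is nonincreasing once feasible", {
  spec <- make_surrogate(seed = 6, dim = 2)
  res <- pec_optimize(surrogate_problem(spec),
                      pec_config(seed = 9, renormalize = FALSE,
                                 n_samples = 300L),
                      qc_backend_surrogate(spec))
  e <- res$trace$best_energy[is.finite(res$trace$best_energy)]
  expect_true(all(diff(e) <= 0))
  # constraint soundness: delta_bar recomputed from the best coefficients
  prob <- surrogate_problem(spec)
  prob$sigma_ideal <- res$sigma_ideal
  redo <- objective_delta(res$best_coefficients, prob,
                          qc_backend_surrogate(spec))
  expect_lt(abs(redo - res$delta_bar), 1e-6)
})

test_that("an unreachable diapason returns the start flagged infeasible", {
  spec <- make_surrogate(seed = 13, dim = 2)
  prob <- surrogate_problem(spec)
  be <- qc_backend_surrogate(spec)
  cfg <- pec_config(seed = 5, diapason = 1e-12, renormalize = FALSE,
                    n_samples = 50L, max_rounds = 3L)
  res <- pec_optimize(prob, cfg, be)
  expect_false(res$feasible)
  expect_identical(res$best_coefficients, res$start_coefficients)
})

test_that("an always-failing backend raises a typed error carrying the trace", {
  spec <- make_surrogate(seed = 2, dim = 2)
  prob <- surrogate_problem(spec)
  prob$sigma_ideal <- c(1, 2, 3)   # targets present, backend still dies
  broken <- qc_backend_function(function(...) stop("SCF blew up"),
                                name = "broken", cache = FALSE)
  cfg <- pec_config(seed = 1, n_samples = 10L, max_rounds = 2L,
                    renormalize = FALSE)
  err <- tryCatch(pec_optimize(prob, cfg, broken), error = identity)
  expect_s3_class(err, "pec_all_invalid")
  expect_s3_class(err$trace, "tbl_df")
})

test_that("column renormalization pins the dominant coefficient at one", {
  cf <- cbind(c(0.2, -0.8, 0.1), c(0.05, 0, 0.5))
  rn <- pecnmr:::renormalize_columns(cf)
  expect_identical(rn[2, 1], 1)
  expect_identical(rn[3, 2], 1)
  # columns are scalar multiples of the originals
  expect_equal(rn[, 1] * cf[2, 1], cf[, 1], tolerance = 1e-12)
})

test_that("tidy/glance expose the optimization trace and summary", {
  spec <- make_surrogate(seed = 17, dim = 1)
  res <- pec_optimize(surrogate_problem(spec),
                      pec_config(seed = 2, renormalize = FALSE,
                                 n_samples = 100L, max_rounds = 15L),
                      qc_backend_surrogate(spec))
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_identical(nrow(g), 1L)
  expect_true(g$feasible)
})
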