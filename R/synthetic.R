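# Seeded generators of synthetic inputs: quadratic shielding/energy
# landscapes for exercising the PEC loop without a quantum-chemistry
# engine, shift datasets drawn from a known affine map plus noise and
# outliers, and the three fitting-molecule geometries.

#' Generate a surrogate shielding/energy landscape
#'
#' Builds, per fitting molecule (acetylene, ethylene, methane), a quadratic
#' property map `sigma(c) = sigma* + (c - c_sigma)' Q_sigma (c - c_sigma)`
#' and energy map `E(c) = E* + (c - c_E)' Q_E (c - c_E)` over a
#' `dim`-dimensional contraction-coefficient vector. All molecules share
#' the property center, so the property deviation vanishes there and the
#' feasible set for a 0.01 ppm diapason is nonempty by construction; the
#' energy centers are displaced from it, so the constrained optimum sits on
#' the trade-off between property and energy. The base property values are
#' the canonical carbon targets 108.06, 50.87 and 192.94 ppm.
#'
#' @param seed RNG seed; the spec is reproducible and pure.
#' @param dim Number of free coefficients (1..6).
#' @return A `surrogate_spec` (fields `dim`, `seed`, `variable`,
#'   `molecules`), consumable by [qc_backend_surrogate()].
#' @export
make_surrogate <- function(seed, dim = 2L) {
  dim <- as.integer(dim)
  if (dim < 1L || dim > 6L) stop("dim must be in 1..6", call. = FALSE)
  base <- list(
    acetylene = list(sigma_star = 108.06, e_star = -77.33),
    ethylene  = list(sigma_star = 50.87,  e_star = -78.59),
    methane   = list(sigma_star = 192.94, e_star = -40.52)
  )
  withr::with_seed(seed, {
    c_sigma <- stats::runif(dim, -0.3, 0.3)
    molecules <- lapply(base, function(b) {
      As <- matrix(stats::rnorm(dim * dim), dim)
      Ae <- matrix(stats::rnorm(dim * dim), dim)
      dir <- stats::rnorm(dim)
      dir <- dir / sqrt(sum(dir^2)) * stats::runif(1, 0.3, 0.6)
      list(
        sigma_star = b$sigma_star,
        c_sigma = c_sigma,
        Q_sigma = crossprod(As) / dim + 0.5 * diag(dim),
        e_star = b$e_star,
        c_e = c_sigma + dir,
        Q_e = crossprod(Ae) / dim + 0.5 * diag(dim),
        nucleus = 1L
      )
    })
    structure(
      list(dim = dim, seed = as.integer(seed),
           variable = list(element = "C", l = 1L),
           molecules = molecules),
      class = "surrogate_spec"
    )
  })
}

#' @export
print.surrogate_spec <- function(x, ...) {
  cat(sprintf("<surrogate_spec: dim %d, seed %d, %d fitting molecules>\n",
              x$dim, x$seed, length(x$molecules)))
  invisible(x)
}

#' Build a PEC problem over a surrogate landscape
#'
#' Assembles a tiny basis library whose carbon p-shell holds the `dim` free
#' coefficients of the surrogate spec, attaches the three fitting-molecule
#' geometries, and presets the ideal targets to the landscape's base
#' property values (which the fully uncontracted reference realizes
#' exactly).
#'
#' @param spec A [make_surrogate()] spec.
#' @param start Optional starting coefficient vector (length `dim`);
#'   default is the property center displaced by +0.25 in every component,
#'   i.e. an infeasible starting point the optimizer must recover from.
#' @return A [pec_problem()].
#' @export
surrogate_problem <- function(spec, start = NULL) {
  stopifnot(inherits(spec, "surrogate_spec"))
  d <- spec$dim
  if (is.null(start)) start <- spec$molecules[[1]]$c_sigma + 0.25
  if (length(start) != d) stop("start must have length ", d, call. = FALSE)
  lib <- basis_set_library("surrogate", list(
    element_basis("C", list(
      basis_shell(0L, c(70, 10), cbind(c(0.3, 0.8))),
      basis_shell(1L, 10 * 2^-(seq_len(d) - 1L), cbind(start))
    )),
    element_basis("H", list(
      basis_shell(0L, c(13, 2), cbind(c(0.2, 0.9)))
    ))
  ))
  mols <- fixture_molecules()
  fitting <- lapply(names(spec$molecules), function(nm) {
    list(molecule = mols[[nm]], nuclei = spec$molecules[[nm]]$nucleus)
  })
  pec_problem(
    fitting, variable = spec$variable, library = lib,
    sigma_ideal = vapply(spec$molecules, function(m) m$sigma_star, numeric(1))
  )
}

#' Describe a synthetic chemical-shift dataset
#'
#' The stated world mirrors the benchmark's shape: 23 natural-product-like
#' compounds carrying 713 proton or 767 carbon shifts in total, generated
#' from a known affine shielding-to-shift map `delta = A * sigma + B` with
#' Gaussian residual noise and a small fraction of large outliers (the
#' un-modelled rovibrational/conformational errors real data carries).
#' Defaults per nucleus kind: slope -1 with intercepts 31.5 ppm (1H) and
#' 186 ppm (13C); residual sd 0.36 / 2.5 ppm, placing the folded-normal
#' CMAE limit `sd * sqrt(2/pi)` at the benchmark's observed accuracy
#' levels (~0.29 / ~2.0 ppm); 2% outliers of magnitude 1.3 / 9 ppm.
#'
#' @param nucleus `"1H"` or `"13C"`.
#' @param seed RNG seed.
#' @param A,B True slope and intercept of the affine map (ppm scale).
#' @param sd Residual noise standard deviation (ppm).
#' @param outlier_fraction Fraction of records displaced as outliers
#'   (in `[0, 1)`).
#' @param outlier_magnitude Displacement magnitude of an outlier (ppm).
#' @param n_compounds Number of compounds.
#' @param n_shifts Total number of shift records.
#' @return A `synthetic_shift_spec`.
#' @export
synthetic_shift_spec <- function(nucleus = c("1H", "13C"), seed = 1L,
                                 A = -1, B = NULL, sd = NULL,
                                 outlier_fraction = 0.02,
                                 outlier_magnitude = NULL,
                                 n_compounds = 23L, n_shifts = NULL) {
  nucleus <- match.arg(nucleus)
  defaults <- if (nucleus == "1H") {
    list(B = 31.5, sd = 0.36, outlier_magnitude = 1.3, n_shifts = 713L,
         range = c(0.5, 9.5))
  } else {
    list(B = 186, sd = 2.5, outlier_magnitude = 9, n_shifts = 767L,
         range = c(5, 200))
  }
  spec <- list(
    nucleus = nucleus, seed = as.integer(seed), A = A,
    B = B %||% defaults$B, sd = sd %||% defaults$sd,
    outlier_fraction = outlier_fraction,
    outlier_magnitude = outlier_magnitude %||% defaults$outlier_magnitude,
    n_compounds = as.integer(n_compounds),
    n_shifts = as.integer(n_shifts %||% defaults$n_shifts),
    delta_range = defaults$range
  )
  stopifnot(spec$sd >= 0, spec$outlier_fraction >= 0,
            spec$outlier_fraction < 1, spec$A != 0,
            spec$n_compounds >= 1, spec$n_shifts >= spec$n_compounds)
  structure(spec, class = "synthetic_shift_spec")
}

#' Generate a synthetic shift dataset
#'
#' Draws true shifts uniformly over the nucleus's chemical-shift range,
#' inverts the affine map to obtain computed shieldings, then perturbs the
#' experimental shifts with Gaussian noise and sign-symmetric outliers.
#' Byte-identical for a fixed spec.
#'
#' @param spec A [synthetic_shift_spec()].
#' @return A shift-record tibble (see [read_shift_table()] for columns).
#' @export
make_shift_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_shift_spec"))
  n <- spec$n_shifts
  withr::with_seed(spec$seed, {
    sizes <- rep(n %/% spec$n_compounds, spec$n_compounds)
    extra <- n %% spec$n_compounds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    compound <- rep(sprintf("cmpd%02d", seq_len(spec$n_compounds)), sizes)
    site <- unlist(lapply(sizes, function(k) {
      sprintf("%s%d", if (spec$nucleus == "1H") "H" else "C", seq_len(k))
    }))
    delta_true <- stats::runif(n, spec$delta_range[1], spec$delta_range[2])
    sigma_calc <- (delta_true - spec$B) / spec$A
    delta_exp <- delta_true + stats::rnorm(n, 0, spec$sd)
    is_outlier <- stats::runif(n) < spec$outlier_fraction
    delta_exp <- delta_exp + is_outlier * spec$outlier_magnitude *
      sample(c(-1, 1), n, replace = TRUE)
    tibble::tibble(
      compound_id = compound, nucleus = spec$nucleus, site = site,
      sigma_calc = sigma_calc, delta_exp = delta_exp, n_equivalent = 1L
    )
  })
}

#' The three fitting molecules
#'
#' Acetylene, ethylene and methane: small molecules spanning a wide range
#' of carbon shieldings (sp, sp2, sp3), used both for optimizing
#' contraction coefficients and for contraction-error measurement. The
#' shipped XYZ fixtures carry synthetic equilibrium geometries with
#' standard hybrid-DFT-quality bond lengths (headers record this); carbons
#' come first, so atom 1 is always a spectator carbon.
#'
#' @return Named list of [molecule()] objects
#'   (`acetylene`, `ethylene`, `methane`).
#' @export
fixture_molecules <- function() {
  dir <- system.file("extdata", "geometries", package = "pecnmr",
                     mustWork = TRUE)
  mols <- lapply(c(acetylene = "acetylene.xyz", ethylene = "ethylene.xyz",
                   methane = "methane.xyz"),
                 function(f) read_xyz(file.path(dir, f)))
  for (nm in names(mols)) mols[[nm]]$name <- nm
  mols
}

#' Canonical fitting set (molecule + spectator carbon)
#'
#' @return List of `list(molecule =, nuclei = 1L)` entries over
#'   [fixture_molecules()], ready for [pec_problem()] or
#'   [measure_contraction_error()].
#' @export
fitting_set <- function() {
  lapply(fixture_molecules(), function(m) list(molecule = m, nuclei = 1L))
}

#' Load the synthetic pecS-like basis libraries
#'
#' The published property-energy consistent sets are tabulated in their
#' paper appendix / supplementary material and are not redistributed here;
#' these stand-ins (so labelled in the shipped files) reproduce the
#' published contraction *schemes* and therefore the exact function
#' counts -- 5 (H) and 18 (C) at level 1, 14 (H) and 34 (C) at level 2 --
#' with invented even-tempered exponents and placeholder coefficients.
#' Structural operations (releasing a p-function, uncontraction, counting,
#' round-tripping) behave exactly as on the real sets.
#'
#' @param n Level, 1 or 2.
#' @return A [basis_set_library()].
#' @export
pecs_synthetic <- function(n = 1L) {
  stopifnot(n %in% c(1L, 2L))
  file <- system.file("extdata",
                      sprintf("pecS-%d-synthetic.basis", as.integer(n)),
                      package = "pecnmr", mustWork = TRUE)
  parse_basis(file = file, name = sprintf("pecS-%d-synthetic", as.integer(n)))
}

#' Write all synthetic fixtures to a directory
#'
#' Emits the three fitting-molecule XYZ files, both synthetic pecS-like
#' basis libraries, and seeded 1H/13C synthetic shift tables.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the shift tables.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(mols <- fixture_molecules())) {
    p <- file.path(dir, paste0(nm, ".xyz"))
    write_xyz(mols[[nm]], p)
    paths <- c(paths, p)
  }
  for (n in 1:2) {
    p <- file.path(dir, sprintf("pecS-%d-synthetic.basis", n))
    write_basis(pecs_synthetic(n), p)
    paths <- c(paths, p)
  }
  for (nuc in c("1H", "13C")) {
    p <- file.path(dir, sprintf("shifts-%s.csv", sub("^\\d+", "", nuc)))
    readr::write_csv(make_shift_dataset(synthetic_shift_spec(nuc, seed = seed)),
                     p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
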