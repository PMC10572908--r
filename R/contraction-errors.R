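# Contraction-quality metrics: how much contracting a basis perturbs the
# isotropic shieldings of the fitting nuclei relative to a fully
# uncontracted reference on the spectator atom.

#' Pair contracted and uncontracted shieldings
#'
#' @param sigma_contracted Shieldings (ppm) from the contracted scheme, one
#'   per fitting nucleus.
#' @param sigma_uncontracted Reference shieldings (ppm) from the totally
#'   uncontracted (all shells) scheme on the same nuclei.
#' @param label Scheme identifier.
#' @return A `contraction_comparison` object.
#' @export
contraction_comparison <- function(sigma_contracted, sigma_uncontracted,
                                   label = "scheme") {
  sc <- as.double(sigma_contracted)
  su <- as.double(sigma_uncontracted)
  if (length(sc) == 0L || length(sc) != length(su)) {
    stop("need >= 1 pair of equal-length shielding vectors", call. = FALSE)
  }
  if (any(!is.finite(sc)) || any(!is.finite(su))) {
    stop("shieldings must be finite", call. = FALSE)
  }
  structure(list(sigma_c = sc, sigma_uc = su, label = label),
            class = "contraction_comparison")
}

#' @export
print.contraction_comparison <- function(x, ...) {
  cat(sprintf("<contraction_comparison '%s': %d pairs, MACE %.4f ppm>\n",
              x$label, length(x$sigma_c), mace(x)))
  invisible(x)
}

#' Mean absolute contraction error (ppm)
#'
#' `MACE = mean |sigma_c - sigma_uc|` over the fitting nuclei: the average
#' absolute deviation of shieldings computed with a contracted scheme from
#' the totally uncontracted reference.
#'
#' @param cmp A [contraction_comparison()].
#' @return MACE in ppm.
#' @export
mace <- function(cmp) {
  stopifnot(inherits(cmp, "contraction_comparison"))
  mean(abs(cmp$sigma_c - cmp$sigma_uc))
}

#' Mean absolute percentage contraction error (percent)
#'
#' `MAPCE = mean( |sigma_c - sigma_uc| / |sigma_uc| ) * 100`. The
#' denominator is taken in absolute value so the metric remains defined
#' for nuclei with negative shieldings; a zero reference shielding is an
#' error naming the offending nucleus.
#'
#' @param cmp A [contraction_comparison()].
#' @return MAPCE in percent.
#' @export
mapce <- function(cmp) {
  stopifnot(inherits(cmp, "contraction_comparison"))
  zero <- which(cmp$sigma_uc == 0)
  if (length(zero)) {
    stop("zero reference shielding for nucleus ", zero[1],
         "; MAPCE undefined", call. = FALSE)
  }
  mean(abs(cmp$sigma_c - cmp$sigma_uc) / abs(cmp$sigma_uc)) * 100
}

#' Reference-protocol assignments for contraction-error measurement
#'
#' Encodes the measurement recipe: the reference shieldings use the
#' spectator element totally uncontracted in all shells, while every other
#' atom keeps the originally contracted library. The contracted side is
#' either the original scheme or (for the hydrogen protocol) the variant
#' with one released p-primitive, i.e. a fully uncontracted p-shell.
#'
#' @param library A [basis_set_library()] (the original contracted sets).
#' @param spectator_element Element whose shieldings are compared.
#' @param contracted `"original"` or `"released-p"` for the contracted side.
#' @return List with `contracted` and `reference` libraries.
#' @export
contraction_reference <- function(library, spectator_element,
                                  contracted = c("original", "released-p")) {
  contracted <- match.arg(contracted)
  sym <- canonical_element(spectator_element)
  reference <- basis_replace(
    library, uncontract_element(basis_lookup(library, sym)))
  reference$name <- paste0(library$name, "-uncontracted-", sym)
  contracted_lib <- switch(contracted,
    original = library,
    `released-p` = released_variant(library, sym, l = 1L)
  )
  list(contracted = contracted_lib, reference = reference)
}

#' Measure contraction errors through a backend
#'
#' Runs the [contraction_reference()] recipe over the fitting molecules and
#' collects the (contracted, uncontracted) shielding pairs of the spectator
#' nuclei.
#'
#' @param backend A `qc_backend`.
#' @param fitting List of `list(molecule =, nuclei =)` entries as in
#'   [pec_problem()]; the nuclei must be atoms of the spectator element.
#' @param library A [basis_set_library()].
#' @param spectator_element Element whose contraction is assessed.
#' @param contracted Passed to [contraction_reference()].
#' @param label Scheme label for the comparison.
#' @return A [contraction_comparison()].
#' @export
measure_contraction_error <- function(backend, fitting, library,
                                      spectator_element,
                                      contracted = "original",
                                      label = NULL) {
  recipe <- contraction_reference(library, spectator_element, contracted)
  grab <- function(lib) {
    unlist(lapply(fitting, function(f) {
      run_shielding(backend, f$molecule, lib,
                    nuclei = f$nuclei)$sigma[as.character(f$nuclei)]
    }))
  }
  contraction_comparison(
    grab(recipe$contracted), grab(recipe$reference),
    label = label %||% paste0(library$name, "/", contracted)
  )
}

#' Tabulate MACE/MAPCE for several schemes
#'
#' @param comparisons List of [contraction_comparison()] objects.
#' @return A tibble with one row per scheme: label, n, mace (ppm),
#'   mapce (percent).
#' @export
contraction_error_table <- function(comparisons) {
  purrr::map_dfr(comparisons, function(cmp) {
    tibble::tibble(label = cmp$label, n = length(cmp$sigma_c),
                   mace = mace(cmp), mapce = mapce(cmp))
  })
}
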