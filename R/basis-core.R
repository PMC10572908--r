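# Data model and structural operations for segmented-contracted Gaussian
# basis sets. Angular momentum is spherical-harmonic counted (p = 3, d = 5,
# f = 7 functions per contracted shell); exponents are stored tight -> diffuse.

SHELL_LETTERS <- c("s", "p", "d", "f")

# Elements of rows 1-3; heavier elements (and ECP blocks) are unsupported.
SUPPORTED_ELEMENTS <- c(
  "H", "He",
  "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"
)

canonical_element <- function(symbol) {
  sym <- paste0(
    toupper(substr(symbol, 1, 1)),
    tolower(substr(symbol, 2, nchar(symbol)))
  )
  if (!sym %in% SUPPORTED_ELEMENTS) {
    stop("unsupported element symbol: '", symbol, "' (rows 1-3 only)",
         call. = FALSE)
  }
  sym
}

#' Construct a contracted Gaussian shell
#'
#' A shell is one angular-momentum block of a segmented-contracted basis:
#' a strictly decreasing vector of primitive exponents and a matrix of
#' contraction coefficients with one row per primitive and one column per
#' contracted function.
#'
#' @param angular_momentum Integer angular momentum (0 = s, 1 = p, 2 = d,
#'   3 = f), or the corresponding letter.
#' @param exponents Positive, strictly decreasing primitive exponents
#'   (bohr^-2).
#' @param coefficients Numeric matrix (primitives x contracted functions),
#'   or a vector for a single contracted function. Coefficients are stored
#'   as published; no renormalization is applied.
#' @return A `basis_shell` object.
#' @examples
#' basis_shell("p", c(4.5, 1.2, 0.3), cbind(c(0.15, 0.60, 0.45)))
#' @export
basis_shell <- function(angular_momentum, exponents, coefficients) {
  if (is.character(angular_momentum)) {
    l <- match(tolower(angular_momentum), SHELL_LETTERS) - 1L
    if (is.na(l)) stop("unknown shell letter: ", angular_momentum, call. = FALSE)
  } else {
    l <- as.integer(angular_momentum)
  }
  if (is.null(dim(coefficients))) coefficients <- cbind(coefficients)
  storage.mode(coefficients) <- "double"
  dimnames(coefficients) <- NULL
  sh <- structure(
    list(l = l, exponents = as.double(exponents), coefficients = coefficients),
    class = "basis_shell"
  )
  validate_basis_shell(sh)
}

validate_basis_shell <- function(sh) {
  l <- sh$l
  z <- sh$exponents
  cf <- sh$coefficients
  if (is.na(l) || l < 0L || l > 3L) {
    stop("angular momentum must be 0..3 (s, p, d, f)", call. = FALSE)
  }
  if (length(z) == 0L || any(!is.finite(z)) || any(z <= 0)) {
    stop("exponents must be positive and finite", call. = FALSE)
  }
  if (any(diff(z) >= 0)) {
    stop("exponents must be strictly decreasing (tight -> diffuse) and unique",
         call. = FALSE)
  }
  if (nrow(cf) != length(z)) {
    stop("coefficient rows (", nrow(cf), ") must equal number of exponents (",
         length(z), ")", call. = FALSE)
  }
  if (ncol(cf) < 1L || ncol(cf) > nrow(cf)) {
    stop("number of contracted functions must be in 1..n_primitives",
         call. = FALSE)
  }
  if (any(!is.finite(cf))) stop("coefficients must be finite", call. = FALSE)
  if (any(colSums(abs(cf)) == 0)) {
    stop("contraction matrix has an all-zero column", call. = FALSE)
  }
  sh
}

#' @export
print.basis_shell <- function(x, ...) {
  cat(sprintf("<basis_shell %s: %d primitives -> %d contracted>\n",
              SHELL_LETTERS[x$l + 1L], length(x$exponents),
              ncol(x$coefficients)))
  invisible(x)
}

#' Construct a per-element basis
#'
#' @param element Chemical symbol (rows 1-3).
#' @param shells List of [basis_shell()] objects, at most one per angular
#'   momentum; stored ordered by increasing angular momentum.
#' @return An `element_basis` object.
#' @export
element_basis <- function(element, shells) {
  sym <- canonical_element(element)
  if (length(shells) == 0L) stop("element basis needs >= 1 shell", call. = FALSE)
  ls <- vapply(shells, function(s) s$l, integer(1))
  if (anyDuplicated(ls)) {
    stop("more than one shell block per angular momentum for ", sym,
         call. = FALSE)
  }
  shells <- shells[order(ls)]
  structure(list(element = sym, shells = shells), class = "element_basis")
}

#' @export
print.element_basis <- function(x, ...) {
  scheme <- contraction_scheme(x)
  cat(sprintf("<element_basis %s (%s)/[%s], %d functions>\n", x$element,
              scheme$primitive, scheme$contracted, count_functions(x)))
  invisible(x)
}

#' Contraction scheme labels such as (7s5p1d)/[4s3p1d]
#'
#' @param eb An `element_basis`.
#' @return List with `primitive` and `contracted` scheme strings.
#' @export
contraction_scheme <- function(eb) {
  prim <- paste0(vapply(eb$shells, function(s)
    paste0(length(s$exponents), SHELL_LETTERS[s$l + 1L]), character(1)),
    collapse = "")
  ctr <- paste0(vapply(eb$shells, function(s)
    paste0(ncol(s$coefficients), SHELL_LETTERS[s$l + 1L]), character(1)),
    collapse = "")
  list(primitive = prim, contracted = ctr)
}

#' Construct a basis-set library
#'
#' A named collection of per-element bases. Element lookup is
#' case-insensitive; a missing element is a defined error.
#'
#' @param name Library name (e.g. a basis-set family label).
#' @param entries List of [element_basis()] objects.
#' @return A `basis_set_library` object.
#' @export
basis_set_library <- function(name, entries) {
  syms <- vapply(entries, function(e) e$element, character(1))
  if (anyDuplicated(syms)) {
    stop("duplicate element in library: ", syms[duplicated(syms)][1],
         call. = FALSE)
  }
  names(entries) <- syms
  structure(list(name = name, entries = entries), class = "basis_set_library")
}

#' @export
print.basis_set_library <- function(x, ...) {
  cat(sprintf("<basis_set_library '%s': %s>\n", x$name,
              paste(names(x$entries), collapse = ", ")))
  invisible(x)
}

#' Look up the basis for an element (case-insensitive)
#'
#' @param lib A `basis_set_library`.
#' @param element Chemical symbol.
#' @return The `element_basis` for that element.
#' @export
basis_lookup <- function(lib, element) {
  sym <- canonical_element(element)
  eb <- lib$entries[[sym]]
  if (is.null(eb)) {
    stop("element '", sym, "' not in basis library '", lib$name, "'",
         call. = FALSE)
  }
  eb
}

#' Replace one element's basis in a library
#'
#' @param lib A `basis_set_library`.
#' @param eb An `element_basis`; replaces (or adds) the entry for its element.
#' @return The modified library.
#' @export
basis_replace <- function(lib, eb) {
  stopifnot(inherits(eb, "element_basis"))
  lib$entries[[eb$element]] <- eb
  lib
}

#' Count contracted basis functions
#'
#' Spherical-harmonic counting: each contracted function of angular momentum
#' `l` contributes `2l + 1` basis functions (p = 3, d = 5, f = 7). This is
#' the convention that gives the published pecS-1/pecS-2 sizes of 5/14
#' functions for hydrogen and 18/34 for carbon.
#'
#' @param x A `basis_shell` or `element_basis`.
#' @return Integer number of basis functions.
#' @export
count_functions <- function(x) UseMethod("count_functions")

#' @export
count_functions.basis_shell <- function(x) {
  as.integer(ncol(x$coefficients) * (2L * x$l + 1L))
}

#' @export
count_functions.element_basis <- function(x) {
  sum(vapply(x$shells, count_functions, integer(1)))
}

#' Count basis functions for a whole molecule
#'
#' Sums [count_functions()] over all atoms under a per-atom basis
#' assignment. This is the `N` entering the `(N/N0)^3` cost model of
#' DFT shielding calculations.
#'
#' @param mol A [molecule()].
#' @param assignment Either a `basis_set_library` (each atom gets its
#'   element's entry) or a list of `element_basis` objects, one per atom.
#' @return Integer total function count (0 for an empty molecule).
#' @export
count_molecular_functions <- function(mol, assignment) {
  stopifnot(inherits(mol, "molecule"))
  n <- length(mol$elements)
  if (n == 0L) return(0L)
  per_atom <- resolve_assignment(mol, assignment)
  sum(vapply(per_atom, count_functions, integer(1)))
}

# Normalize an assignment to a per-atom list of element_basis.
resolve_assignment <- function(mol, assignment) {
  n <- length(mol$elements)
  if (inherits(assignment, "basis_set_library")) {
    lapply(seq_len(n), function(i) basis_lookup(assignment, mol$elements[i]))
  } else if (is.list(assignment)) {
    if (length(assignment) != n) {
      stop("per-atom assignment has ", length(assignment),
           " entries for ", n, " atoms", call. = FALSE)
    }
    for (i in seq_len(n)) {
      if (!inherits(assignment[[i]], "element_basis")) {
        stop("atom ", i, " has no assigned basis", call. = FALSE)
      }
    }
    assignment
  } else {
    stop("assignment must be a basis_set_library or per-atom list",
         call. = FALSE)
  }
}

#' Fully uncontract a shell
#'
#' Replaces the contraction matrix by the identity, so every primitive
#' becomes its own basis function. Exponents are unchanged; idempotent.
#'
#' @param sh A `basis_shell`.
#' @return The uncontracted `basis_shell`.
#' @export
uncontract_shell <- function(sh) {
  stopifnot(inherits(sh, "basis_shell"))
  n <- length(sh$exponents)
  basis_shell(sh$l, sh$exponents, diag(n))
}

#' Fully uncontract every shell of an element basis
#'
#' This is the reference construction for contraction-error metrics: the
#' spectator atom is described totally uncontracted in all shells.
#'
#' @param eb An `element_basis`.
#' @return The uncontracted `element_basis`.
#' @export
uncontract_element <- function(eb) {
  stopifnot(inherits(eb, "element_basis"))
  element_basis(eb$element, lapply(eb$shells, uncontract_shell))
}

# Is primitive i already a released (free) function: a unit column exists
# whose only nonzero entry is row i, and row i is zero elsewhere.
primitive_is_free <- function(sh, i) {
  cf <- sh$coefficients
  row_nz <- which(abs(cf[i, ]) > 0)
  length(row_nz) == 1L && sum(abs(cf[, row_nz]) > 0) == 1L
}

#' Release one primitive into its own contracted function
#'
#' Moves the selected primitive out of the contracted combination(s) it
#' participates in and gives it a unit column of its own, increasing the
#' contracted count by exactly one (i.e. by `2l + 1` basis functions).
#' Releasing one p-function is the transformation behind the "mod"
#' (less contracted) variants of shielding-oriented basis sets; for a
#' hydrogen p-shell contracted to one function from two primitives it
#' yields a fully uncontracted p-shell.
#'
#' @param sh A `basis_shell` with more primitives than contracted functions.
#' @param which Primitive index in tight-to-diffuse order; default picks the
#'   primitive with the largest absolute-coefficient spread across the
#'   contracted functions (ties broken towards the tighter primitive).
#' @return A `basis_shell` with one more contracted function.
#' @export
release_primitive <- function(sh, which = NULL) {
  stopifnot(inherits(sh, "basis_shell"))
  n <- length(sh$exponents)
  k <- ncol(sh$coefficients)
  if (n < 2L || k >= n) {
    stop("nothing to release: shell is already fully uncontracted",
         call. = FALSE)
  }
  if (is.null(which)) {
    cand <- which(!vapply(seq_len(n), primitive_is_free, logical(1), sh = sh))
    if (length(cand) == 0L) stop("nothing to release", call. = FALSE)
    # weight spread of a primitive across the contracted functions; for a
    # single-column shell this reduces to the dominant |coefficient|
    spread <- apply(abs(sh$coefficients[cand, , drop = FALSE]), 1,
                    function(r) max(r) - if (length(r) > 1L) min(r) else 0)
    which <- cand[which.max(spread)]
  }
  which <- as.integer(which)
  if (which < 1L || which > n) stop("primitive index out of range", call. = FALSE)
  if (primitive_is_free(sh, which)) {
    stop("primitive ", which, " is already a free function", call. = FALSE)
  }
  cf <- sh$coefficients
  cf[which, ] <- 0
  if (any(colSums(abs(cf)) == 0)) {
    stop("releasing primitive ", which,
         " would empty an existing contracted function", call. = FALSE)
  }
  unit <- numeric(n)
  unit[which] <- 1
  basis_shell(sh$l, sh$exponents, cbind(cf, unit, deparse.level = 0))
}

#' Release a primitive of one shell inside a library
#'
#' Convenience wrapper producing the "mod" variant of a library: the given
#' element's shell of angular momentum `l` gets one primitive released.
#'
#' @param lib A `basis_set_library`.
#' @param element Chemical symbol.
#' @param l Angular momentum of the shell to modify (default 1 = p).
#' @param which Primitive index, see [release_primitive()].
#' @return The modified library, renamed with a `-mod` suffix.
#' @export
released_variant <- function(lib, element, l = 1L, which = NULL) {
  eb <- basis_lookup(lib, element)
  idx <- which(vapply(eb$shells, function(s) s$l, integer(1)) == l)
  if (length(idx) != 1L) {
    stop("no ", SHELL_LETTERS[l + 1L], " shell on ", eb$element, call. = FALSE)
  }
  eb$shells[[idx]] <- release_primitive(eb$shells[[idx]], which = which)
  out <- basis_replace(lib, eb)
  out$name <- paste0(lib$name, "-mod")
  out
}
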