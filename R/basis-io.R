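# Basis-set text I/O.
#
# Two dialects:
#  * "table": element header line, then per-shell header "<L> <n_prim>
#    <n_contr>", then one row per primitive "exponent c1 c2 ...".
#    Blank lines and '#'/'!' comments are ignored.
#  * "gaussian": element-keyed blocks as used by major QC programs
#    ("<El> 0", shell entries "<letter> <n_prim> <scale>", terminated by
#    "****"); SP entries are split into separate s and p blocks.
#
# Numerals are written with 17 significant digits so doubles round-trip
# bit-exactly; published coefficient tables are stored as-is (no
# renormalization on import or export).

#' Parse a basis-set library from text
#'
#' @param text Character scalar (or vector of lines) holding the basis
#'   definition; alternatively give `file`.
#' @param file Path to a basis file.
#' @param dialect `"table"` (native dialect, supports general contraction
#'   matrices directly) or `"gaussian"` (element-keyed segmented blocks).
#' @param name Library name; defaults to the file name or "basis".
#' @return A [basis_set_library()].
#' @details Multiple blocks of the same angular momentum within one element
#'   (the segmented serialization of a general contraction) are merged into
#'   a single block over the union of their primitives, with a warning.
#' @export
parse_basis <- function(text = NULL, file = NULL,
                        dialect = c("table", "gaussian"), name = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    if (is.null(file)) stop("give either text or file", call. = FALSE)
    text <- readr::read_lines(file)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
  }
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (is.null(name)) name <- "basis"
  lines <- sub("[#!].*$", "", text)
  switch(dialect,
    table = parse_basis_table(lines, name),
    gaussian = parse_basis_gaussian(lines, name)
  )
}

parse_error <- function(lineno, msg) {
  stop(sprintf("basis parse error at line %d: %s", lineno, msg), call. = FALSE)
}

split_fields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1]]

# Element vs shell headers are distinguished by field count, not by the
# symbol itself: "S" alone is sulfur, "s 4 2" is an s-shell header.
is_symbol_token <- function(tok) grepl("^[A-Za-z]{1,2}$", tok)

parse_basis_table <- function(lines, name) {
  entries <- list()
  i <- 1L
  n <- length(lines)
  current_sym <- NULL
  current_shells <- NULL

  flush_element <- function() {
    if (is.null(current_sym)) return()
    if (length(current_shells) == 0L) {
      stop("element ", current_sym, " has no shells", call. = FALSE)
    }
    eb <- element_basis(current_sym, merge_same_l(current_shells, current_sym))
    if (!is.null(entries[[eb$element]])) {
      stop("duplicate element block: ", eb$element, call. = FALSE)
    }
    entries[[eb$element]] <<- eb
  }

  while (i <= n) {
    fields <- split_fields(lines[i])
    if (length(fields) == 0L || fields[1] == "") { i <- i + 1L; next }
    if (length(fields) == 1L && is_symbol_token(fields[1])) {
      flush_element()
      current_sym <- fields[1]
      current_shells <- list()
      i <- i + 1L
      next
    }
    if (is.null(current_sym)) parse_error(i, "shell data before element header")
    if (length(fields) != 3L) {
      parse_error(i, paste0("expected shell header '<L> <n_prim> <n_contr>', got '",
                            trimws(lines[i]), "'"))
    }
    l_tok <- fields[1]
    n_prim <- suppressWarnings(as.integer(fields[2]))
    n_ctr <- suppressWarnings(as.integer(fields[3]))
    if (is.na(n_prim) || is.na(n_ctr)) parse_error(i, "bad shell header counts")
    rows <- matrix(NA_real_, n_prim, n_ctr + 1L)
    for (r in seq_len(n_prim)) {
      i <- i + 1L
      if (i > n) parse_error(i, "unexpected end of input inside shell block")
      vals <- suppressWarnings(as.numeric(split_fields(lines[i])))
      if (length(vals) != n_ctr + 1L || any(is.na(vals))) {
        parse_error(i, sprintf("expected %d numbers (exponent + %d coefficients)",
                               n_ctr + 1L, n_ctr))
      }
      rows[r, ] <- vals
    }
    sh <- tryCatch(
      basis_shell(l_tok, rows[, 1], rows[, -1, drop = FALSE]),
      error = function(e) parse_error(i, conditionMessage(e))
    )
    current_shells <- c(current_shells, list(sh))
    i <- i + 1L
  }
  flush_element()
  if (length(entries) == 0L) stop("no element blocks found", call. = FALSE)
  basis_set_library(name, unname(entries))
}

# Merge shells sharing an angular momentum into one block over the union of
# their primitives (zero coefficients where a primitive is absent from a
# contracted function). Warns: the input was general-contraction-style.
merge_same_l <- function(shells, sym) {
  ls <- vapply(shells, function(s) s$l, integer(1))
  if (!anyDuplicated(ls)) return(shells)
  warning("element ", sym, ": multiple blocks of one angular momentum; ",
          "merged into segmented blocks over the primitive union",
          call. = FALSE)
  lapply(sort(unique(ls)), function(l) {
    grp <- shells[ls == l]
    if (length(grp) == 1L) return(grp[[1]])
    z <- sort(unique(unlist(lapply(grp, function(s) s$exponents))),
              decreasing = TRUE)
    cols <- do.call(cbind, lapply(grp, function(s) {
      m <- matrix(0, length(z), ncol(s$coefficients))
      m[match(s$exponents, z), ] <- s$coefficients
      m
    }))
    basis_shell(l, z, cols)
  })
}

parse_basis_gaussian <- function(lines, name) {
  entries <- list()
  i <- 1L
  n <- length(lines)
  sp_warned <- FALSE
  while (i <= n) {
    fields <- split_fields(lines[i])
    if (length(fields) == 0L || fields[1] == "" || fields[1] == "****") {
      i <- i + 1L; next
    }
    if (length(fields) != 2L || !is_symbol_token(fields[1])) {
      parse_error(i, "expected element header '<El> 0'")
    }
    sym <- fields[1]
    shells <- list()
    i <- i + 1L
    repeat {
      if (i > n) parse_error(i, "missing '****' terminator")
      fields <- split_fields(lines[i])
      if (length(fields) >= 1L && fields[1] == "****") { i <- i + 1L; break }
      if (length(fields) == 0L || fields[1] == "") { i <- i + 1L; next }
      letter <- toupper(fields[1])
      n_prim <- suppressWarnings(as.integer(fields[2]))
      if (is.na(n_prim)) parse_error(i, "bad primitive count")
      want <- if (letter == "SP") 3L else 2L
      rows <- matrix(NA_real_, n_prim, want)
      for (r in seq_len(n_prim)) {
        i <- i + 1L
        vals <- suppressWarnings(as.numeric(gsub("[dD]", "e",
                                                 split_fields(lines[i]))))
        if (length(vals) != want || any(is.na(vals))) {
          parse_error(i, sprintf("expected %d numbers", want))
        }
        rows[r, ] <- vals
      }
      if (letter == "SP") {
        if (!sp_warned) {
          warning("SP (general contraction) entries split into segmented ",
                  "s and p blocks", call. = FALSE)
          sp_warned <- TRUE
        }
        shells <- c(shells,
                    list(basis_shell(0L, rows[, 1], rows[, 2]),
                         basis_shell(1L, rows[, 1], rows[, 3])))
      } else {
        lidx <- match(tolower(letter), SHELL_LETTERS) - 1L
        if (is.na(lidx)) parse_error(i, paste("unknown shell letter", letter))
        shells <- c(shells, list(basis_shell(lidx, rows[, 1], rows[, 2])))
      }
      i <- i + 1L
    }
    eb <- element_basis(sym, suppressWarnings(merge_same_l(shells, sym)))
    if (!is.null(entries[[eb$element]])) {
      stop("duplicate element block: ", eb$element, call. = FALSE)
    }
    entries[[eb$element]] <- eb
  }
  if (length(entries) == 0L) stop("no element blocks found", call. = FALSE)
  basis_set_library(name, unname(entries))
}

fmt_num <- function(x) sprintf("%.16e", x)

#' Serialize a basis-set library
#'
#' @param lib A [basis_set_library()].
#' @param file Optional path; when given, lines are written there.
#' @param dialect `"table"` or `"gaussian"` (see [parse_basis()]).
#' @return The text lines, invisibly when `file` is given. Numerals carry
#'   17 significant digits so `parse_basis(write_basis(lib))` is exact.
#' @export
write_basis <- function(lib, file = NULL, dialect = c("table", "gaussian")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(lib, "basis_set_library"))
  out <- switch(dialect,
    table = write_basis_table(lib),
    gaussian = write_basis_gaussian(lib)
  )
  if (!is.null(file)) {
    readr::write_lines(out, file)
    return(invisible(out))
  }
  out
}

write_basis_table <- function(lib) {
  unlist(lapply(lib$entries, function(eb) {
    c(eb$element,
      unlist(lapply(eb$shells, function(sh) {
        c(sprintf("%s %d %d", SHELL_LETTERS[sh$l + 1L],
                  length(sh$exponents), ncol(sh$coefficients)),
          vapply(seq_along(sh$exponents), function(r) {
            paste(c(fmt_num(sh$exponents[r]), fmt_num(sh$coefficients[r, ])),
                  collapse = "  ")
          }, character(1)))
      })),
      "")
  }), use.names = FALSE)
}

write_basis_gaussian <- function(lib) {
  unlist(lapply(lib$entries, function(eb) {
    body <- unlist(lapply(eb$shells, function(sh) {
      # one segmented entry per contracted function, nonzero primitives only
      unlist(lapply(seq_len(ncol(sh$coefficients)), function(j) {
        nz <- which(abs(sh$coefficients[, j]) > 0)
        c(sprintf("%s   %d   1.00", toupper(SHELL_LETTERS[sh$l + 1L]),
                  length(nz)),
          vapply(nz, function(r) {
            paste0("      ", fmt_num(sh$exponents[r]), "  ",
                   fmt_num(sh$coefficients[r, j]))
          }, character(1)))
      }))
    }))
    c(sprintf("%s 0", eb$element), body, "****")
  }), use.names = FALSE)
}
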