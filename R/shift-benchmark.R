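# Linear-scaling benchmark protocol for chemical shifts: computed isotropic
# shieldings are mapped onto experimental shifts by one ordinary
# least-squares line per nucleus kind and basis scheme
# (delta_exp = A * sigma_calc + B), scaled shifts are restored from the
# fitted line, and accuracy is scored as the corrected mean absolute error
# (CMAE) between scaled and experimental shifts. Because slope and
# intercept are refitted, CMAE is invariant under any affine transform of
# the computed shieldings: it measures scatter, not systematic offset.

SHIFT_COLUMNS <- c("compound_id", "nucleus", "site", "sigma_calc",
                   "delta_exp", "n_equivalent")

validate_shift_records <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"n_equivalent" %in% names(records)) records$n_equivalent <- 1L
  missing <- setdiff(SHIFT_COLUMNS, names(records))
  if (length(missing)) {
    stop("shift table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(records$sigma_calc) | !is.finite(records$delta_exp))
  if (length(bad)) {
    stop("non-finite sigma_calc/delta_exp at row ", bad[1], call. = FALSE)
  }
  bad <- which(!records$nucleus %in% c("1H", "13C"))
  if (length(bad)) {
    stop("row ", bad[1], ": nucleus must be '1H' or '13C', got '",
         records$nucleus[bad[1]], "'", call. = FALSE)
  }
  bad <- which(records$n_equivalent < 1 |
                 records$n_equivalent != round(records$n_equivalent))
  if (length(bad)) {
    stop("row ", bad[1], ": n_equivalent must be a positive integer",
         call. = FALSE)
  }
  records
}

#' Read a shift benchmark table
#'
#' Delimited text (comma or tab, auto-detected from the header line) with
#' columns `compound_id, nucleus, site, sigma_calc, delta_exp` and optional
#' `n_equivalent`. `nucleus` is `"1H"` or `"13C"`; `sigma_calc` is the
#' computed isotropic shielding (ppm) and `delta_exp` the experimental
#' chemical shift (ppm). Validation errors carry the offending row number.
#'
#' @param file Path to the table.
#' @return A validated tibble of shift records.
#' @export
read_shift_table <- function(file) {
  header <- readr::read_lines(file, n_max = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  records <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                               trim_ws = TRUE)
  validate_shift_records(records)
}

#' Average computed shieldings over equivalent nuclei
#'
#' Magnetically equivalent sites (e.g. methyl protons) carry one
#' experimental shift; this collapses rows sharing
#' (compound, nucleus, site) into a single record whose `sigma_calc` is the
#' mean of the individual computed shieldings and whose `n_equivalent`
#' counts the merged sites. Tables that are already averaged (one row per
#' site with `n_equivalent` set) pass through unchanged.
#'
#' @param records A shift-record tibble.
#' @return A collapsed tibble.
#' @export
collapse_equivalent <- function(records) {
  records <- validate_shift_records(records)
  records |>
    dplyr::group_by(.data$compound_id, .data$nucleus, .data$site) |>
    dplyr::summarise(
      sigma_calc = mean(.data$sigma_calc),
      delta_exp = .data$delta_exp[1],
      n_equivalent = sum(.data$n_equivalent),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(SHIFT_COLUMNS))
}

#' Fit the shielding-to-shift regression
#'
#' Ordinary least squares of `delta_exp` on `sigma_calc`, fitted globally
#' across all compounds of one nucleus kind and one basis scheme. The slope
#' of a shielding-to-shift map is near -1; the fit is unconstrained.
#'
#' @param records Shift records (one nucleus kind; pass `nucleus` to subset
#'   a mixed table).
#' @param nucleus Optional `"1H"`/`"13C"` filter.
#' @param scheme Label of the basis scheme the shieldings came from.
#' @return A `shift_model` with slope `A`, intercept `B` and the underlying
#'   `lm` fit.
#' @export
fit_shift_model <- function(records, nucleus = NULL, scheme = "basis") {
  records <- validate_shift_records(records)
  if (!is.null(nucleus)) {
    records <- dplyr::filter(records, .data$nucleus == !!nucleus)
  }
  kinds <- unique(records$nucleus)
  if (length(kinds) != 1L) {
    stop("records span nucleus kinds ", paste(kinds, collapse = ", "),
         "; fit one kind at a time", call. = FALSE)
  }
  if (nrow(records) < 2L || length(unique(records$sigma_calc)) < 2L) {
    stop("degenerate regression: need >= 2 distinct sigma_calc values",
         call. = FALSE)
  }
  fit <- stats::lm(delta_exp ~ sigma_calc, data = records)
  A <- unname(stats::coef(fit)[2])
  if (A == 0) stop("degenerate regression: zero slope", call. = FALSE)
  structure(
    list(A = A, B = unname(stats::coef(fit)[1]), nucleus = kinds,
         scheme = scheme, n_points = nrow(records), fit = fit),
    class = "shift_model"
  )
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf(
    "<shift_model %s/%s: delta = %.5f * sigma + %.3f ppm (n = %d)>\n",
    x$nucleus, x$scheme, x$A, x$B, x$n_points))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.shift_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept_B", "slope_A"),
    estimate = c(x$B, x$A),
    std.error = unname(s[, "Std. Error"]),
    nucleus = x$nucleus, scheme = x$scheme
  )
}

#' @exportS3Method generics::glance
glance.shift_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(A = x$A, B = x$B, r.squared = s$r.squared,
                 sigma = s$sigma, n = x$n_points,
                 nucleus = x$nucleus, scheme = x$scheme)
}

#' Restore scaled chemical shifts from computed shieldings
#'
#' `delta_scaled = A * sigma_calc + B` per record, using the fitted line of
#' the matching nucleus kind.
#'
#' @param records Shift records.
#' @param model A [fit_shift_model()] result of the same nucleus kind.
#' @return The records tibble with a `delta_scaled` column appended.
#' @export
scale_shifts <- function(records, model) {
  stopifnot(inherits(model, "shift_model"))
  records <- validate_shift_records(records)
  if (!all(records$nucleus == model$nucleus)) {
    stop("records contain ", paste(setdiff(unique(records$nucleus),
                                           model$nucleus), collapse = ", "),
         " rows but the model was fitted for ", model$nucleus, call. = FALSE)
  }
  dplyr::mutate(records,
                delta_scaled = model$A * .data$sigma_calc + model$B)
}

#' Score a benchmark with the corrected mean absolute error
#'
#' CMAE is the mean of `|delta_scaled - delta_exp|` over all N records of a
#' nucleus kind, the scaled shifts coming from the global regression.
#' Outliers are ranked and reported, never removed: the statistic is meant
#' to be read together with its largest deviations.
#'
#' @param records Shift records (one nucleus kind).
#' @param model A matching [fit_shift_model()]; fitted from `records` when
#'   omitted.
#' @param outlier_threshold Absolute residual (ppm) above which a record is
#'   listed as an outlier; default 3 times the CMAE.
#' @return A `benchmark_stats` object: `cmae` (ppm), `n`, `per_compound`
#'   MAE tibble, ranked `outliers` tibble, and the model used.
#' @export
cmae <- function(records, model = NULL, outlier_threshold = NULL) {
  records <- validate_shift_records(records)
  if (nrow(records) == 0L) stop("empty record set", call. = FALSE)
  if (is.null(model)) model <- fit_shift_model(records)
  scored <- scale_shifts(records, model) |>
    dplyr::mutate(abs_error = abs(.data$delta_scaled - .data$delta_exp))
  value <- mean(scored$abs_error)
  thr <- outlier_threshold %||% (3 * value)
  per_compound <- scored |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(n = dplyr::n(), mae = mean(.data$abs_error),
                     .groups = "drop")
  outliers <- scored |>
    dplyr::filter(.data$abs_error > thr) |>
    dplyr::arrange(dplyr::desc(.data$abs_error))
  structure(
    list(cmae = value, n = nrow(scored), per_compound = per_compound,
         outliers = outliers, records = scored, model = model,
         outlier_threshold = thr),
    class = "benchmark_stats"
  )
}

#' @export
print.benchmark_stats <- function(x, ...) {
  cat(sprintf(
    "<benchmark_stats %s/%s: CMAE = %.3f ppm over %d shifts, %d outlier(s) > %.2f ppm>\n",
    x$model$nucleus, x$model$scheme, x$cmae, x$n, nrow(x$outliers),
    x$outlier_threshold))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.benchmark_stats <- function(x, ...) x$per_compound

#' @exportS3Method generics::glance
glance.benchmark_stats <- function(x, ...) {
  tibble::tibble(cmae = x$cmae, n = x$n, n_outliers = nrow(x$outliers),
                 max_abs_error = max(x$records$abs_error),
                 A = x$model$A, B = x$model$B,
                 nucleus = x$model$nucleus, scheme = x$model$scheme)
}

#' @exportS3Method ggplot2::autoplot
autoplot.benchmark_stats <- function(object, type = c("correlation", "residuals"),
                                     ...) {
  type <- match.arg(type)
  if (type == "correlation") {
    ggplot2::ggplot(object$records,
                    ggplot2::aes(x = .data$sigma_calc, y = .data$delta_exp)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_abline(slope = object$model$A,
                           intercept = object$model$B, colour = "red") +
      ggplot2::labs(
        x = "computed isotropic shielding (ppm)",
        y = "experimental chemical shift (ppm)",
        title = sprintf("%s / %s: CMAE %.3f ppm (n = %d)",
                        object$model$nucleus, object$model$scheme,
                        object$cmae, object$n)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$per_compound,
                    ggplot2::aes(x = stats::reorder(.data$compound_id, .data$mae),
                                 y = .data$mae)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = "compound", y = "MAE of scaled shifts (ppm)",
                    title = "per-compound accuracy") +
      ggplot2::theme_minimal()
  }
}

#' Relative cost of a basis-set scheme under cubic DFT scaling
#'
#' Computational cost of DFT shielding calculations grows roughly as the
#' cube of the basis-set size, so `(N/N0)^3` estimates the operation count
#' of a scheme with `N` contracted functions relative to a baseline with
#' `N0` (e.g. the smallest double-zeta scheme on a given molecule; compare
#' [count_molecular_functions()]).
#'
#' @param N Function count of the scheme of interest.
#' @param N0 Baseline function count (> 0).
#' @return The dimensionless cost ratio `(N/N0)^3`.
#' @export
cost_ratio <- function(N, N0) {
  if (any(N0 <= 0)) stop("baseline function count N0 must be positive",
                         call. = FALSE)
  (N / N0)^3
}
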