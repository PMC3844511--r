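#' Observed multinomial cell counts
#'
#' Constructors for the three count vectors the likelihood consumes:
#' `triad_counts()` takes the 10 triad cells `n1..n10` (ordering per
#' [triad_cells()]), `dyad_counts()` the 7 dyad cells `m1..m7` (per
#' [dyad_cells()]) and `monad_counts()` the affected-singleton genotype
#' counts in order `(AA, Aa, aa)` (i.e. `s2, s1, s0`).  Counts must be
#' nonnegative integers; any vector may be all zero.
#'
#' @param x numeric vector of cell counts of the appropriate length.
#' @return A classed integer vector (`triad_counts`, `dyad_counts` or
#'   `monad_counts`).
#' @examples
#' triad_counts(c(1, 2, 2, 2, 1, 2, 1, 2, 2, 1))
#' monad_counts(c(AA = 4, Aa = 10, aa = 6))
#' @export
triad_counts <- function(x = integer(10)) {
  .make_counts(x, 10L, .TRIAD_LABELS, "triad_counts")
}

#' @rdname triad_counts
#' @export
dyad_counts <- function(x = integer(7)) {
  .make_counts(x, 7L, .DYAD_LABELS, "dyad_counts")
}

#' @rdname triad_counts
#' @export
monad_counts <- function(x = integer(3)) {
  .make_counts(x, 3L, .MONAD_LABELS, "monad_counts")
}

.make_counts <- function(x, len, labels, class) {
  if (inherits(x, class)) return(x)
  if (!is.numeric(x) || length(x) != len)
    stop("expected a numeric vector of ", len, " cell counts", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  structure(setNames(as.integer(round(x)), labels), class = class)
}

#' Combined family dataset
#'
#' A dataset is a triple of count vectors - triads, parent-child dyads and
#' affected monads - that together define the joint multinomial likelihood.
#' Any component may be empty (all-zero).
#'
#' @param triads a [triad_counts()] vector (or length-10 numeric).
#' @param dyads a [dyad_counts()] vector (or length-7 numeric).
#' @param monads a [monad_counts()] vector (or length-3 numeric, order
#'   `AA, Aa, aa`).
#' @return An object of class `family_dataset`.
#' @examples
#' family_dataset(triads = c(1, 2, 2, 2, 1, 2, 1, 2, 2, 1))
#' @export
family_dataset <- function(triads = integer(10), dyads = integer(7),
                           monads = integer(3)) {
  structure(list(triads = triad_counts(triads),
                 dyads = dyad_counts(dyads),
                 monads = monad_counts(monads)),
            class = "family_dataset")
}

#' @export
print.family_dataset <- function(x, ...) {
  cat(sprintf("Family dataset: %d triads, %d dyads, %d monads\n",
              sum(x$triads), sum(x$dyads), sum(x$monads)))
  cat("  triads:", paste0(names(x$triads), "=", x$triads, collapse = " "), "\n")
  cat("  dyads: ", paste0(names(x$dyads), "=", x$dyads, collapse = " "), "\n")
  cat("  monads:", paste0(names(x$monads), "=", x$monads, collapse = " "), "\n")
  invisible(x)
}

#' Restrict a dataset to the family types used in an analysis
#'
#' `"FT"` keeps full triads only, `"FT+PD"` adds parent-child dyads,
#' `"FT+PD+AM"` (default) uses everything including affected monads.
#' Components outside the subset are zeroed, so all likelihoods and tests
#' downstream ignore them.
#'
#' @param data a [family_dataset()].
#' @param data_used one of `"FT+PD+AM"`, `"FT+PD"`, `"FT"`.
#' @return A [family_dataset()].
#' @export
subset_dataset <- function(data, data_used = c("FT+PD+AM", "FT+PD", "FT")) {
  data_used <- match.arg(toupper(data_used), c("FT+PD+AM", "FT+PD", "FT"))
  stopifnot(inherits(data, "family_dataset"))
  if (data_used == "FT")
    data$dyads <- dyad_counts(integer(7))
  if (data_used %in% c("FT", "FT+PD"))
    data$monads <- monad_counts(integer(3))
  data
}
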