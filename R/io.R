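.parse_geno <- function(x) {
  x <- trimws(x)
  out <- rep(NA_integer_, length(x))
  missing <- is.na(x) | x %in% c("", ".", "?") | toupper(x) == "NA"
  hom_ref <- x == "AA" | x == "2"
  het <- x == "Aa" | x == "aA" | x == "1"
  hom_alt <- x == "aa" | x == "0"
  out[hom_ref] <- 2L
  out[het] <- 1L
  out[hom_alt] <- 0L
  bad <- !missing & !hom_ref & !het & !hom_alt
  attr(out, "bad") <- which(bad)
  out
}

.GENO_LABELS <- c("aa", "Aa", "AA")  # dosage 0, 1, 2

#' Read a tab-delimited family genotype file
#'
#' One row per family, header columns `family_id`, `father`, `mother`,
#' `child` (case-insensitive names).  Genotypes are written `AA` / `Aa` /
#' `aa` (heterozygotes may be `aA`) or as the dosage `2` / `1` / `0` of the
#' risk allele A; missing parents are `NA`, empty, or `.`.  The affected
#' child's genotype may never be missing.  Malformed genotypes or missing
#' child genotypes abort the read with the offending line numbers.
#'
#' The risk allele (the one whose relative risks `psi1`, `psi2` are
#' modelled) is the allele written `A` / counted by the dosage.  The model
#' is not symmetric under allele relabelling, so no automatic
#' minor-allele flipping is performed; pass `risk_allele = "a"` to swap the
#' coding at read time instead.
#'
#' @param path file path.
#' @param risk_allele `"A"` (default) or `"a"`.
#' @return A data frame of class `family_records` with character columns
#'   `family_id`, `father`, `mother`, `child` (`AA`/`Aa`/`aa`, `NA` for a
#'   missing parent).
#' @export
read_families <- function(path, risk_allele = c("A", "a")) {
  risk_allele <- match.arg(risk_allele)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", strip.white = TRUE,
                    na.strings = character())
  names(raw) <- tolower(names(raw))
  need <- c("family_id", "father", "mother", "child")
  if (!all(need %in% names(raw)))
    stop("family file must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  geno <- lapply(raw[c("father", "mother", "child")], .parse_geno)
  bad_lines <- sort(unique(unlist(lapply(geno, attr, "bad"))))
  no_child <- which(is.na(geno$child))
  problems <- character()
  if (length(bad_lines))
    problems <- c(problems, paste0("unrecognized genotype on data line(s) ",
                                   paste(bad_lines, collapse = ", ")))
  if (length(no_child))
    problems <- c(problems, paste0("missing child genotype on data line(s) ",
                                   paste(no_child, collapse = ", ")))
  if (length(problems))
    stop("invalid family file '", path, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  if (risk_allele == "a")
    geno <- lapply(geno, function(g) 2L - g)
  out <- data.frame(
    family_id = raw$family_id,
    father = .GENO_LABELS[geno$father + 1L],
    mother = .GENO_LABELS[geno$mother + 1L],
    child = .GENO_LABELS[geno$child + 1L],
    stringsAsFactors = FALSE)
  class(out) <- c("family_records", "data.frame")
  out
}

# cell lookup keyed by "hi lo child" parental-dosage / child-dosage triples
.TRIAD_CELL_KEY <- c("2 2 2" = 1L, "2 1 2" = 2L, "2 1 1" = 3L, "2 0 1" = 4L,
                     "1 1 2" = 5L, "1 1 1" = 6L, "1 1 0" = 7L, "1 0 1" = 8L,
                     "1 0 0" = 9L, "0 0 0" = 10L)
.DYAD_CELL_KEY <- c("2 2" = 1L, "2 1" = 2L, "1 2" = 3L, "1 1" = 4L,
                    "1 0" = 5L, "0 1" = 6L, "0 0" = 7L)

#' Tabulate family records into multinomial cell counts
#'
#' Maps each record to its likelihood cell: triads (both parents observed)
#' to `n1..n10` by unordered parental mating type and child genotype, dyads
#' (exactly one parent observed, either sex) to `m1..m7`, and monads to the
#' child genotype counts.  Families whose child genotype is Mendelian-
#' impossible given the observed parent(s) (for example an AA parent with
#' an aa child) are excluded from the counts and reported, not thrown.
#'
#' @param records a `family_records` data frame from [read_families()] (or
#'   any data frame with columns `family_id`, `father`, `mother`, `child`
#'   coded `AA`/`Aa`/`aa`/`NA`).
#' @return A list of class `tabulation_report`: `counts` (a
#'   [family_dataset()]), `n_excluded_mendelian`,
#'   `n_excluded_uninformative` (reserved, always 0 under the current
#'   exclusion rules) and `exclusions` (a data frame of excluded records
#'   with reasons).  Included plus excluded records always sum to the
#'   input.
#' @export
tabulate_families <- function(records) {
  stopifnot(all(c("family_id", "father", "mother", "child") %in%
                  names(records)))
  to_dosage <- function(x) c(aa = 0L, Aa = 1L, AA = 2L)[as.character(x)]
  fd <- to_dosage(records$father)
  md <- to_dosage(records$mother)
  cd <- to_dosage(records$child)
  if (anyNA(cd)) stop("child genotype may not be missing", call. = FALSE)

  tri <- integer(10); dy <- integer(7); mo <- integer(3)
  excl <- list()
  is_triad <- !is.na(fd) & !is.na(md)
  is_dyad <- xor(is.na(fd), is.na(md))
  for (i in seq_along(cd)) {
    if (is_triad[i]) {
      key <- paste(max(fd[i], md[i]), min(fd[i], md[i]), cd[i])
      cell <- .TRIAD_CELL_KEY[key]
      if (is.na(cell)) {
        excl[[length(excl) + 1L]] <- data.frame(
          family_id = records$family_id[i], type = "triad",
          reason = "Mendelian-inconsistent child genotype",
          stringsAsFactors = FALSE)
      } else tri[cell] <- tri[cell] + 1L
    } else if (is_dyad[i]) {
      pg <- if (is.na(fd[i])) md[i] else fd[i]
      cell <- .DYAD_CELL_KEY[paste(pg, cd[i])]
      if (is.na(cell)) {
        excl[[length(excl) + 1L]] <- data.frame(
          family_id = records$family_id[i], type = "dyad",
          reason = "Mendelian-inconsistent child genotype",
          stringsAsFactors = FALSE)
      } else dy[cell] <- dy[cell] + 1L
    } else {
      mo[3L - cd[i]] <- mo[3L - cd[i]] + 1L  # (AA, Aa, aa) order
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(family_id = character(), type = character(),
               reason = character(), stringsAsFactors = FALSE)
  n_mend <- nrow(exclusions)
  if (n_mend > 0)
    warning(n_mend, " record(s) excluded as Mendelian-inconsistent",
            call. = FALSE)
  structure(list(counts = family_dataset(tri, dy, mo),
                 n_excluded_mendelian = n_mend,
                 n_excluded_uninformative = 0L,
                 exclusions = exclusions),
            class = "tabulation_report")
}

#' @export
print.tabulation_report <- function(x, ...) {
  print(x$counts)
  cat(sprintf("  excluded: %d Mendelian-inconsistent\n",
              x$n_excluded_mendelian))
  invisible(x)
}
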