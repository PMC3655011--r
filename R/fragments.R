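# Physicochemical filtering of fragment libraries and property summaries.
# Descriptors are inputs (vendor-supplied tables); nothing is recomputed
# from structures here.

#' Physicochemical filter specification
#'
#' Named inclusive ranges over fragment descriptors. The default reproduces
#' the Lipinski-style screen used to cut a 50,000-compound vendor library to
#' a fragment set: molecular weight 200-500 Da, logP -5 to 2, molar
#' refractivity 40-130 m^3/mol, total atom count 20-70, and polar surface
#' area at most 200 A^2. All bounds are inclusive.
#'
#' @param MW,logP,MR,n_atoms,PSA length-2 numeric ranges `c(lower, upper)`;
#'   use `-Inf`/`Inf` for open ends.
#' @param ... further named ranges over any descriptor column.
#' @return object of class `filter_spec`: a named list of ranges.
#' @export
filter_spec <- function(MW = c(200, 500), logP = c(-5, 2), MR = c(40, 130),
                        n_atoms = c(20, 70), PSA = c(-Inf, 200), ...) {
  spec <- c(list(MW = MW, logP = logP, MR = MR, n_atoms = n_atoms, PSA = PSA),
            list(...))
  for (nm in names(spec)) {
    r <- spec[[nm]]
    if (length(r) != 2L || !is.numeric(r) || r[1L] > r[2L])
      stop("range for ", nm, " must be numeric c(lower, upper) with lower <= upper")
  }
  structure(spec, class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("fragment filter (inclusive bounds):\n")
  for (nm in names(x))
    cat(sprintf("  %-8s [%g, %g]\n", nm, x[[nm]][1L], x[[nm]][2L]))
  invisible(x)
}

#' Apply the filter to a single fragment record
#'
#' @param record named list or one-row data.frame of descriptors.
#' @param spec a [filter_spec()].
#' @return list with `pass` (logical) and `violations` (character vector of
#'   descriptor names out of range; empty when passing).
#' @export
apply_filter <- function(record, spec) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  miss <- setdiff(names(spec), names(record))
  if (length(miss))
    stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  viol <- character(0)
  for (nm in names(spec)) {
    v <- record[[nm]]
    if (is.na(v)) stop("missing descriptor(s): ", nm)
    r <- spec[[nm]]
    if (v < r[1L] || v > r[2L]) viol <- c(viol, nm)
  }
  list(pass = length(viol) == 0L, violations = viol)
}

#' Filter a fragment library table
#'
#' Vectorised equivalent of applying [apply_filter()] to every row; input
#' row order is preserved in the output.
#'
#' @param table data.frame of fragment records, one row per compound, with a
#'   `compound_id` column and the descriptor columns named in `spec`.
#' @param spec a [filter_spec()].
#' @return list with `passed` (the passing subset), `report` (list:
#'   `n_input`, `n_pass`, `n_fail`, `violations` — named integer vector of
#'   per-descriptor violation counts).
#' @export
filter_library <- function(table, spec) {
  if (!nrow(table)) stop("empty input: fragment table has no rows")
  miss <- setdiff(names(spec), names(table))
  if (length(miss))
    stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  ok <- rep(TRUE, nrow(table))
  viol <- setNames(integer(length(spec)), names(spec))
  for (nm in names(spec)) {
    r <- spec[[nm]]
    bad <- table[[nm]] < r[1L] | table[[nm]] > r[2L]
    viol[nm] <- sum(bad)
    ok <- ok & !bad
  }
  list(passed = table[ok, , drop = FALSE],
       report = list(n_input = nrow(table), n_pass = sum(ok),
                     n_fail = sum(!ok), violations = viol))
}

#' Per-descriptor means and histograms of a fragment table
#'
#' Arithmetic means plus fixed-width histogram counts (10 equal-width bins
#' over the observed range per descriptor) for library-distribution plots.
#'
#' @param table data.frame of fragment records.
#' @param properties descriptor columns to summarise; default every numeric
#'   column except `compound_id`.
#' @param n_bins number of equal-width bins (default 10).
#' @return list with `means` (named numeric) and `histograms` (named list of
#'   data.frames with `mid`, `lower`, `upper`, `count`).
#' @export
property_summary <- function(table, properties = NULL, n_bins = 10L) {
  if (!nrow(table)) stop("empty input: fragment table has no rows")
  if (is.null(properties)) {
    properties <- names(table)[vapply(table, is.numeric, logical(1))]
    properties <- setdiff(properties, "compound_id")
  }
  means <- vapply(properties, function(nm) mean(table[[nm]]), numeric(1))
  histograms <- lapply(properties, function(nm) {
    v <- table[[nm]]
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    data.frame(mid = (br[-1L] + br[-(n_bins + 1L)]) / 2,
               lower = br[-(n_bins + 1L)], upper = br[-1L], count = cnt)
  })
  names(histograms) <- properties
  list(means = means, histograms = histograms)
}

#' Read a fragment property table
#'
#' CSV with one row per compound; header gives descriptor names
#' (`compound_id`, `MW`, `logP`, `logS`, `MR`, `n_atoms`, `HAC`, `nHA`,
#' `NR`, `HD`, `HA`, `PSA` in the canonical layout).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_fragment_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a fragment property table
#' @param table data.frame of fragment records.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
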