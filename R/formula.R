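#' @name formula
#' @title Elemental formulas and exact monoisotopic mass arithmetic
#'
#' @description
#' A `chem_formula` is a named integer vector of element counts plus a signed
#' integer charge. All downstream annotation (transformation products,
#' neutral-loss fragments) is arithmetic on these objects: masses are sums of
#' fixed monoisotopic atomic masses, and ions subtract one electron mass per
#' positive charge so that, e.g., the protonated parent of MDMB-4en-PINACA
#' (C20H28N3O3+) evaluates to m/z 358.2125 rather than 358.2131.
NULL

# Monoisotopic masses of the most abundant isotope (Da). Fixed digit strings;
# deliberately no external mass-table dependency so reported m/z are stable.
.atomic_mass <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668,
  Si = 27.9769265325
)

.electron_mass <- 0.00054857990
.proton_mass   <- 1.00727646688
.neutron_gap   <- 1.0033548378  # 13C - 12C spacing, Da

#' Round half away from zero
#'
#' Reported m/z and ppm values use commercial ("half-up") rounding rather than
#' R's banker's rounding, so 4-decimal m/z and 1-decimal ppm values match the
#' convention of vendor software and published tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.5, 0)   # 1, not 0
#' round_half_up(358.21251820, 4)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon absorbs float representation error just below .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Parse a molecular formula string
#'
#' Accepts strings of element symbols with optional counts and an optional
#' trailing charge written as repeated sign characters, e.g. `"H2O"`,
#' `"C20H28N3O3+"`, `"C6H5O-"`, `"C2H8N2++"`. Repeated elements are summed.
#'
#' @param text formula string.
#' @return A `chem_formula`: list with `counts` (named integer vector) and
#'   `charge` (integer).
#' @export
#' @examples
#' parse_formula("C20H28N3O3+")
#' parse_formula("H2O")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty formula string")

  # trailing charge: '+', '-', '++', '--', ... (charge = number of signs)
  charge <- 0L
  m <- regmatches(text, regexpr("[+-]+$", text))
  if (length(m)) {
    signs <- strsplit(m, "")[[1]]
    if (length(unique(signs)) > 1L) stop("mixed charge signs in '", text, "'")
    charge <- if (signs[1] == "+") length(signs) else -length(signs)
    text <- sub("[+-]+$", "", text)
  }
  if (!nzchar(text)) stop("formula has charge but no atoms")

  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(parts)) != nchar(text))
    stop("malformed formula token in '", text, "'")

  counts <- integer(0)
  for (p in parts) {
    el <- regmatches(p, regexpr("^[A-Z][a-z]?", p))
    n <- sub("^[A-Z][a-z]?", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.atomic_mass))
      stop("unknown element symbol '", el, "'")
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  new_formula(counts, charge)
}

#' @rdname parse_formula
#' @param counts named non-negative integer vector of element counts.
#' @param charge signed integer charge.
#' @export
new_formula <- function(counts, charge = 0L) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative element count")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "chem_formula")
}

#' Render a formula back to text (Hill order: C, H, then alphabetical)
#'
#' @param f a `chem_formula`.
#' @return character scalar; `parse_formula(format_formula(f))` round-trips.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  els <- names(f$counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  body <- paste0(vapply(ord, function(e) {
    n <- f$counts[[e]]
    paste0(e, if (n > 1L) n else "")
  }, character(1)), collapse = "")
  ch <- f$charge
  paste0(body, strrep(if (ch >= 0L) "+" else "-", abs(ch)))
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x),
      "  (monoisotopic ", sprintf("%.4f", monoisotopic_mz(x)),
      if (x$charge == 0L) " Da)" else " Th)", "\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a formula (Da)
#'
#' @param f a `chem_formula`.
#' @return sum of per-atom monoisotopic masses; the charge is ignored here.
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  if (length(f$counts) == 0L) stop("empty formula")
  sum(.atomic_mass[names(f$counts)] * f$counts)
}

#' Monoisotopic m/z of an ion
#'
#' For a charged species, one electron mass is subtracted per positive charge
#' (added per negative charge) and the result is divided by |charge|. A
#' neutral formula returns its monoisotopic mass.
#'
#' @param f a `chem_formula`.
#' @return m/z in Th (or Da for neutral `f`), unrounded.
#' @export
#' @examples
#' monoisotopic_mz(parse_formula("C20H28N3O3+"))  # 358.21252 -> prints 358.2125
monoisotopic_mz <- function(f) {
  m <- monoisotopic_mass(f)
  z <- f$charge
  if (z == 0L) return(m)
  (m - z * .electron_mass) / abs(z)
}

#' Relative mass deviation in ppm, table-reporting convention
#'
#' The calculated m/z is first rounded half-up to 4 decimals (the precision
#' at which it is reported), then `1e6 * (recorded - calculated)/calculated`
#' is rounded half-up to 1 decimal.
#'
#' @param recorded measured m/z.
#' @param calculated theoretical m/z (> 0).
#' @return signed ppm deviation, 1 decimal.
#' @export
#' @examples
#' ppm_error(358.2129, monoisotopic_mz(parse_formula("C20H28N3O3+")))  # 1.1
ppm_error <- function(recorded, calculated) {
  stopifnot(calculated > 0)
  calc4 <- round_half_up(calculated, 4)
  round_half_up(1e6 * (recorded - calc4) / calc4, 1)
}

# raw (unrounded, no reporting convention) ppm difference, used for matching
.ppm_diff <- function(a, b) 1e6 * abs(a - b) / b

#' Formula addition and subtraction
#'
#' @param f,g `chem_formula` objects. The charge of `f` is kept.
#' @return a `chem_formula`. Subtraction errors if any count would go
#'   negative (the operation must stay element-legal).
#' @export
formula_add <- function(f, g) {
  counts <- f$counts
  for (el in names(g$counts))
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + g$counts[[el]]
  new_formula(counts, f$charge)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f, g) {
  counts <- f$counts
  for (el in names(g$counts)) {
    have <- if (el %in% names(counts)) counts[[el]] else 0L
    if (have < g$counts[[el]])
      stop("insufficient ", el, " to subtract ", format_formula(g),
           " from ", format_formula(f))
    counts[el] <- have - g$counts[[el]]
  }
  new_formula(counts, f$charge)
}

#' Biotransformation deltas
#'
#' A `transformation_delta` is a named gain/loss pair of formula fragments
#' (e.g. hydroxylation = gain of one O). Its exact mass delta is
#' `mass(add) - mass(remove)` and is cached at construction.
#'
#' @param name label, e.g. `"hydroxylation"`.
#' @param add,remove formula strings (or `chem_formula`) gained / lost;
#'   either may be empty (`""`).
#' @return a `transformation_delta` with fields `name`, `add`, `remove`,
#'   `exact_delta` (Da), `n_atoms` (atoms changed).
#' @export
transformation_delta <- function(name, add = "", remove = "") {
  as_f <- function(x) {
    if (inherits(x, "chem_formula")) return(x)
    if (!nzchar(x)) return(new_formula(integer(0)))
    parse_formula(x)
  }
  add <- as_f(add); remove <- as_f(remove)
  mass0 <- function(f) if (length(f$counts)) monoisotopic_mass(f) else 0
  structure(list(
    name = name, add = add, remove = remove,
    exact_delta = mass0(add) - mass0(remove),
    n_atoms = sum(add$counts) + sum(remove$counts)
  ), class = "transformation_delta")
}

#' Default electrochemical transformation library
#'
#' Gains/losses commonly produced in EC oxidation cells: hydroxylation (+O),
#' dihydroxylation (+2O), dehydrogenated dihydroxylation (+2O-2H, the quinone
#' route), dehydrogenation (-2H), oxidation to carbonyl (+O-2H),
#' demethylation (-CH2), demethylation with hydroxylation (-CH2+O) and
#' hydration (+H2O). Extensible via [read_transformation_library()].
#'
#' @return list of `transformation_delta` objects.
#' @export
default_transformations <- function() {
  list(
    transformation_delta("hydroxylation",                 add = "O"),
    transformation_delta("dihydroxylation",               add = "O2"),
    transformation_delta("dehydrogenated dihydroxylation", add = "O2", remove = "H2"),
    transformation_delta("dehydrogenation",               remove = "H2"),
    transformation_delta("oxidation to carbonyl",         add = "O", remove = "H2"),
    transformation_delta("demethylation",                 remove = "CH2"),
    transformation_delta("demethylation + hydroxylation", add = "O", remove = "CH2"),
    transformation_delta("hydration",                     add = "H2O")
  )
}

#' Read a transformation library from a plain-text config
#'
#' One transformation per line: `name <TAB or ,> add-formula <TAB or ,>
#' remove-formula`; empty fragments allowed; `#` comments and blank lines
#' ignored.
#'
#' @param path file path.
#' @return list of `transformation_delta` objects.
#' @export
read_transformation_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    parts <- trimws(strsplit(l, "[\t,]")[[1]])
    length(parts) <- 3L
    parts[is.na(parts)] <- ""
    transformation_delta(parts[1], parts[2], parts[3])
  })
}

#' Match an observed mass difference against a transformation library
#'
#' @param delta_da observed mass difference (Da), signed.
#' @param library list of `transformation_delta`; default
#'   [default_transformations()].
#' @param tol_da absolute tolerance in Da (> 0); default 0.001 (1 mDa),
#'   generous against the sub-ppm mass accuracy of modern QTOF instruments.
#' @return list of matching `transformation_delta`s, each with an added
#'   `match_error_da`, ranked by ascending |error| then by fewer atoms
#'   changed. Empty list if nothing matches.
#' @export
#' @examples
#' match_mass_difference(15.9949)[[1]]$name  # "hydroxylation"
match_mass_difference <- function(delta_da, library = default_transformations(),
                                  tol_da = 0.001) {
  stopifnot(tol_da > 0)
  errs <- vapply(library, function(d) abs(delta_da - d$exact_delta), numeric(1))
  keep <- which(errs <= tol_da)
  if (!length(keep)) return(list())
  atoms <- vapply(library[keep], function(d) d$n_atoms, numeric(1))
  ord <- order(errs[keep], atoms)
  out <- library[keep][ord]
  for (i in seq_along(out)) out[[i]]$match_error_da <- errs[keep][ord][i]
  out
}

#' Apply a transformation delta to a formula
#'
#' @param f parent `chem_formula`.
#' @param d a `transformation_delta`.
#' @return the transformed `chem_formula`; charge unchanged. Errors when `f`
#'   lacks the atoms the delta removes.
#' @export
#' @examples
#' format_formula(apply_delta(parse_formula("C20H28N3O3+"),
#'                            transformation_delta("hydroxylation", add = "O")))
apply_delta <- function(f, d) {
  stopifnot(inherits(f, "chem_formula"), inherits(d, "transformation_delta"))
  out <- f
  if (length(d$add$counts)) out <- formula_add(out, d$add)
  if (length(d$remove$counts)) out <- formula_subtract(out, d$remove)
  out
}
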