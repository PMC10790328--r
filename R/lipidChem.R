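# Molecular-formula arithmetic and the built-in glycerophospholipid mass
# table used for native-MS adduct assignment and spectrum simulation.

# IUPAC standard atomic weights (average) and principal-isotope masses
# (monoisotopic), 4+ decimal places, baked in for reproducibility.
.ATOMIC_WEIGHTS <- list(
  average = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
              P = 30.9738, S = 32.06, Na = 22.9898),
  monoisotopic = c(H = 1.007825, C = 12.0, N = 14.003074, O = 15.994915,
                   P = 30.973762, S = 31.972071, Na = 22.989769)
)

# Proton mass used for positive-ion m/z arithmetic.
.PROTON_MASS <- 1.00728

#' Parse a molecular formula in Hill notation
#'
#' Converts a formula string such as `"C45H83O13P"` into a named integer
#' count vector. Only elements with registered atomic weights (C, H, N, O,
#' P, S, Na) are accepted. The empty string is the empty formula.
#'
#' @param formula character(1) formula in Hill notation.
#' @return named integer vector of element counts.
#' @examples
#' parseFormula("HPO3")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!nzchar(formula)) return(stats::setNames(integer(), character()))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  tokens <- regmatches(formula, m)[[1]]
  if (sum(nchar(tokens)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", tokens)
  ct <- as.integer(ifelse(grepl("[0-9]$", tokens),
                          sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(el, names(.ATOMIC_WEIGHTS$average))
  if (length(unknown))
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "))
  counts <- tapply(ct, factor(el, levels = unique(el)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

# Element-wise sum of count vectors; negative results are rejected.
.formulaCombine <- function(a, b, sign = 1L) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + sign * b
  if (any(out < 0)) stop("formula arithmetic produced negative counts")
  out[out > 0]
}

#' Add or subtract molecular formulas
#'
#' @param a,b formulas as Hill-notation strings or named count vectors.
#' @return named integer count vector.
#' @export
formulaAdd <- function(a, b) {
  .formulaCombine(.asCounts(a), .asCounts(b), 1L)
}

#' @rdname formulaAdd
#' @export
formulaSubtract <- function(a, b) {
  .formulaCombine(.asCounts(a), .asCounts(b), -1L)
}

.asCounts <- function(x) {
  if (is.character(x)) return(parseFormula(x))
  stopifnot(is.numeric(x), !is.null(names(x)) || length(x) == 0)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  x
}

#' Format a count vector as a Hill-notation string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically.
#'
#' @param counts named integer vector of element counts.
#' @return character(1).
#' @export
formulaString <- function(counts) {
  counts <- .asCounts(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1) e else paste0(e, counts[[e]])
  }, ""), collapse = "")
}

#' Mass of a molecular formula
#'
#' Sum of count times atomic weight, either average (IUPAC standard atomic
#' weights) or monoisotopic. The empty formula has mass 0.
#'
#' @param formula Hill-notation string or named count vector.
#' @param kind `"average"` (default) or `"monoisotopic"`.
#' @return numeric(1) mass in Da.
#' @examples
#' formulaMass("C45H83O13P")           # di-18:1 phosphatidylinositol, ~863 Da
#' formulaMass("HPO3")                 # phosphate-ladder increment, ~80 Da
#' @export
formulaMass <- function(formula, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  counts <- .asCounts(formula)
  if (!length(counts)) return(0)
  w <- .ATOMIC_WEIGHTS[[kind]]
  unknown <- setdiff(names(counts), names(w))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(counts * w[names(counts)])
}

# Fatty acyl C[n]:[d] as the free fatty acid CnH(2n-2d)O2.
.acylFormula <- function(carbons, doubleBonds) {
  stats::setNames(as.integer(c(carbons, 2 * carbons - 2 * doubleBonds, 2)),
                  c("C", "H", "O"))
}

#' Parse an acyl-chain composition string
#'
#' Accepts the `"Cx:y/Cx:y"` convention (e.g. `"18:1/18:1"`,
#' `"16:0-18:1"`); unknown forms are rejected rather than guessed.
#'
#' @param acyl character(1) such as `"18:1/18:1"` or `"16:0-18:1"`.
#' @return data.frame with columns `carbons`, `doubleBonds` (one row per
#'   chain).
#' @export
parseAcyl <- function(acyl) {
  stopifnot(is.character(acyl), length(acyl) == 1)
  parts <- strsplit(acyl, "[/-]")[[1]]
  ok <- grepl("^[0-9]+:[0-9]+$", parts)
  if (!length(parts) || !all(ok))
    stop("unrecognized acyl composition: ", acyl)
  mat <- do.call(rbind, strsplit(parts, ":"))
  data.frame(carbons = as.integer(mat[, 1]), doubleBonds = as.integer(mat[, 2]))
}

# Head-group alcohols X-OH attached via a phosphoester (one H2O lost).
.HEADGROUPS <- list(
  PA = "",            # phosphatidic acid: no head-group alcohol
  PE = "C2H7NO",      # ethanolamine
  PC = "C5H13NO",     # choline
  PS = "C3H7NO3",     # serine
  PG = "C3H8O3",      # glycerol
  PI = "C6H12O6"      # myo-inositol
)

#' Construct a glycerophospholipid formula from class and acyl chains
#'
#' Builds the free-acid formula of a diacyl glycerophospholipid:
#' glycerol + phosphoric acid + head-group alcohol + two fatty acids, minus
#' one water per ester/phosphoester bond. Phosphoinositide classes
#' (`PI4P`, `PIP2`, `PIP3`) add one HPO3 per phosphate to the PI formula,
#' so the phosphate-ladder spacing is exact by construction.
#'
#' @param class lipid class tag: PA, PE, PC, PS, PG, PI, PI4P, PIP2, PIP3
#'   or S1P.
#' @param acyl acyl composition string (ignored for S1P, which has a fixed
#'   d18:1 backbone).
#' @return named integer count vector.
#' @export
lipidFormula <- function(class, acyl = "18:1/18:1") {
  if (class == "S1P") return(parseFormula("C18H38NO5P"))
  nPhos <- switch(class, PI4P = 1L, PIP2 = 2L, PIP3 = 3L, 0L)
  base <- if (class %in% c("PI4P", "PIP2", "PIP3")) "PI" else class
  if (!base %in% names(.HEADGROUPS)) stop("unknown lipid class: ", class)
  chains <- parseAcyl(acyl)
  if (nrow(chains) != 2) stop("diacyl lipids require two acyl chains")
  f <- parseFormula("C3H8O3")                       # glycerol
  f <- formulaAdd(f, "H3PO4")                       # phosphate
  nBonds <- 3L                                      # 2 esters + 1 phosphoester
  if (nzchar(.HEADGROUPS[[base]])) {
    f <- formulaAdd(f, .HEADGROUPS[[base]])
    nBonds <- nBonds + 1L                           # head-group phosphoester
  }
  for (i in seq_len(nrow(chains)))
    f <- formulaAdd(f, .acylFormula(chains$carbons[i], chains$doubleBonds[i]))
  f <- formulaSubtract(f, stats::setNames(c(2L * nBonds, nBonds), c("H", "O")))
  for (i in seq_len(nPhos)) f <- formulaAdd(f, "HPO3")
  f
}

#' Built-in lipid panel
#'
#' The lipid species used throughout: the phosphoinositide ladder PI,
#' PI(4)P, PI(4,5)P2 and PIP3 with di-oleoyl (18:1/18:1) chains, the
#' 1-palmitoyl-2-oleoyl (16:0-18:1) glycerophospholipids PA, PS, PG, PE
#' and PC, and sphingosine-1-phosphate. All species are modeled as free
#' acids.
#'
#' @return data.frame with columns `name`, `class`, `acyl`, `formula`
#'   (Hill notation), `average_mass`, `monoisotopic_mass` (Da).
#' @examples
#' tab <- lipidTable()
#' tab[tab$class == "PI", ]
#' @export
lipidTable <- function() {
  spec <- rbind(
    data.frame(class = c("PI", "PI4P", "PIP2", "PIP3"), acyl = "18:1/18:1"),
    data.frame(class = c("PA", "PS", "PG", "PE", "PC"), acyl = "16:0-18:1"),
    data.frame(class = "S1P", acyl = "d18:1")
  )
  pretty <- c(PI = "PI", PI4P = "PI(4)P", PIP2 = "PI(4,5)P2",
              PIP3 = "PIP3", PA = "PA", PS = "PS", PG = "PG", PE = "PE",
              PC = "PC", S1P = "S1P")
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    cls <- spec$class[i]
    f <- lipidFormula(cls, if (cls == "S1P") "18:1/18:1" else spec$acyl[i])
    data.frame(
      name = if (cls == "S1P") "S1P"
             else sprintf("%s(%s)", pretty[[cls]], spec$acyl[i]),
      class = cls, acyl = spec$acyl[i], formula = formulaString(f),
      average_mass = formulaMass(f, "average"),
      monoisotopic_mass = formulaMass(f, "monoisotopic")
    )
  })
  do.call(rbind, rows)
}

#' Look up the average mass of a panel lipid
#'
#' @param name lipid `name` or `class` from [lipidTable()].
#' @param kind `"average"` or `"monoisotopic"`.
#' @return numeric(1) mass in Da.
#' @export
lipidMass <- function(name, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  tab <- lipidTable()
  i <- match(name, tab$name)
  if (is.na(i)) i <- match(name, tab$class)
  if (is.na(i)) stop("unknown lipid: ", name)
  tab[[paste0(kind, "_mass")]][i]
}

#' Registered modification mass constants
#'
#' Fixed mass deltas for common protein modifications; currently the
#' N-terminal acetylation (+C2H2O) routinely observed on eukaryotic
#' proteins. The registry is immutable.
#'
#' @return data.frame with columns `name`, `formula`, `average_delta`,
#'   `monoisotopic_delta` (Da).
#' @export
modificationConstants <- function() {
  f <- "C2H2O"
  data.frame(name = "N-terminal acetylation", formula = f,
             average_delta = formulaMass(f, "average"),
             monoisotopic_delta = formulaMass(f, "monoisotopic"))
}

#' Read or write a lipid table CSV
#'
#' The exchange format has columns `name,class,formula` with formulas in
#' Hill notation; masses are recomputed on read so the file cannot carry
#' inconsistent masses.
#'
#' @param path file path.
#' @param table a lipid table as from [lipidTable()] (for writing).
#' @return for `readLipidTable`, a data.frame like [lipidTable()].
#' @export
readLipidTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "class", "formula")
  if (!all(need %in% names(df)))
    stop("lipid table CSV must have columns: ", paste(need, collapse = ", "))
  df$average_mass <- vapply(df$formula, formulaMass, 0, kind = "average")
  df$monoisotopic_mass <- vapply(df$formula, formulaMass, 0,
                                 kind = "monoisotopic")
  df
}

#' @rdname readLipidTable
#' @export
writeLipidTable <- function(table, path) {
  utils::write.csv(table[, c("name", "class", "formula")], path,
                   row.names = FALSE)
  invisible(path)
}
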