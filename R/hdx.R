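# HDX-MS analysis: RFU, differential uptake (delta-RFU), two-ligand
# synergy, coverage metrics, and residue-level projection.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Theoretical maximum deuterium uptake of a peptide
#'
#' N_max = length - 1 - (number of prolines at positions 2..length): the
#' first residue's amide is treated as fully back-exchanged and prolines
#' carry no amide hydrogen. A peptide with N_max = 0 (e.g. a lone
#' proline) is unusable for RFU and is returned as 0.
#'
#' @param sequence character vector of peptide sequences (standard
#'   residues only).
#' @return integer vector of exchange-competent amide counts.
#' @examples
#' maxUptake(c("LLGNDAVKKL", "APGI"))
#' @export
maxUptake <- function(sequence) {
  stopifnot(is.character(sequence))
  vapply(sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    bad <- setdiff(chars, .AA)
    if (length(bad))
      stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
    n <- length(chars)
    max(n - 1L - sum(chars[-1] == "P"), 0L)
  }, 0L, USE.NAMES = FALSE)
}

#' Assemble an HDXDataset from a long uptake table
#'
#' @param uptake data.frame in a DynamX-style state-data layout with
#'   columns `start`, `end`, `sequence`, `state`, `exposure` (minutes),
#'   `replicate`, `uptake` (Da). Column name variants
#'   (`Start`, `End`, `Sequence`, `State`, `Exposure_min`, `Replicate`,
#'   `Uptake_Da`) are accepted.
#' @param exposures the exposure grid in minutes (default
#'   c(1, 60, 180, 360)).
#' @return an [HDXDataset-class].
#' @export
hdxDataset <- function(uptake, exposures = c(1, 60, 180, 360)) {
  map <- c(Start = "start", End = "end", Sequence = "sequence",
           State = "state", Exposure_min = "exposure",
           Replicate = "replicate", Uptake_Da = "uptake")
  hit <- names(uptake) %in% names(map)
  names(uptake)[hit] <- map[names(uptake)[hit]]
  uptake <- uptake[, intersect(c("start", "end", "sequence", "state",
                                 "exposure", "replicate", "uptake"),
                               names(uptake))]
  pep <- unique(uptake[, c("start", "end", "sequence")])
  pep <- pep[order(pep$start, pep$end), ]
  if (any(nchar(pep$sequence) != pep$end - pep$start + 1))
    stop("sequence length must equal end - start + 1")
  pep$nmax <- maxUptake(pep$sequence)
  rownames(pep) <- NULL
  new("HDXDataset", uptake = uptake, peptides = pep,
      exposures = as.numeric(exposures))
}

.pepKey <- function(df) paste(df$start, df$end, sep = "-")

#' Relative fractional uptake (RFU) per peptide, state and exposure
#'
#' RFU = mean(uptake)/N_max with the replicate SD propagated by the same
#' 1/N_max factor. Peptides with N_max = 0 are dropped with a message;
#' cells with fewer replicates than expected are computed with a warning
#' when n >= 2 and are an error when n < 2.
#'
#' @param hdx an [HDXDataset-class].
#' @param expectedReplicates replicates the design calls for (default 3).
#' @return data.frame with columns `start`, `end`, `state`, `exposure`,
#'   `rfu`, `sd`, `n`.
#' @export
computeRfu <- function(hdx, expectedReplicates = 3L) {
  stopifnot(is(hdx, "HDXDataset"))
  u <- hdx@uptake
  pep <- hdx@peptides
  u$nmax <- pep$nmax[match(.pepKey(u), .pepKey(pep))]
  drop <- u$nmax == 0
  if (any(drop)) {
    message("dropping ", sum(drop), " rows with N_max = 0")
    u <- u[!drop, , drop = FALSE]
  }
  agg <- stats::aggregate(uptake ~ start + end + state + exposure + nmax,
                          data = u,
                          FUN = function(v) c(m = mean(v), s = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(agg[c("start", "end", "state", "exposure")],
                    rfu = agg$uptake[, "m"] / agg$nmax,
                    sd = agg$uptake[, "s"] / agg$nmax,
                    n = as.integer(agg$uptake[, "n"]))
  if (any(out$n < 2))
    stop("fewer than 2 replicates for some peptide/state/exposure cells")
  if (any(out$n < expectedReplicates))
    warning("some cells have fewer replicates than expected (",
            expectedReplicates, ")")
  out[order(out$start, out$end, out$state, out$exposure), ]
}

# Per-replicate RFU values for one peptide/state/exposure cell.
.rfuReplicates <- function(u, start, end, state, exposure, nmax) {
  v <- u$uptake[u$start == start & u$end == end & u$state == state &
                u$exposure == exposure]
  v / nmax
}

#' Differential RFU between a ligand-bound state and apo
#'
#' Per peptide and exposure, delta-RFU = RFU_state - RFU_apo with a
#' two-tailed unpaired (Welch) t-test on the replicate RFU values.
#' Peptides present in only one of the two states are excluded with a
#' message. Rows are ordered by peptide start then end (heatmap-ready).
#'
#' @param hdx an [HDXDataset-class].
#' @param state the perturbed state label.
#' @param ref the reference state label (default `"apo"`).
#' @param alpha significance threshold (default 0.05).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   `"none"` (default, per-peptide tests as commonly reported) or e.g.
#'   `"BH"`.
#' @return data.frame with columns `start`, `end`, `exposure`, `dRFU`,
#'   `sd` (pooled), `p`, `significant`.
#' @export
deltaRfu <- function(hdx, state, ref = "apo", alpha = 0.05,
                     adjust = "none") {
  stopifnot(is(hdx, "HDXDataset"))
  u <- hdx@uptake
  if (!state %in% u$state) stop("state not present: ", state)
  if (!ref %in% u$state) stop("reference state not present: ", ref)
  pep <- hdx@peptides[hdx@peptides$nmax > 0, , drop = FALSE]
  inState <- function(s) .pepKey(pep) %in% .pepKey(u[u$state == s, ])
  both <- inState(state) & inState(ref)
  if (any(!both))
    message("excluding ", sum(!both), " peptide(s) absent from one state")
  pep <- pep[both, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pep))) for (ex in hdx@exposures) {
    a <- .rfuReplicates(u, pep$start[i], pep$end[i], state, ex, pep$nmax[i])
    b <- .rfuReplicates(u, pep$start[i], pep$end[i], ref, ex, pep$nmax[i])
    if (!length(a) || !length(b)) next
    d <- mean(a) - mean(b)
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(d, 0))) 1 else NA_real_
    } else stats::t.test(a, b, var.equal = FALSE)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      start = pep$start[i], end = pep$end[i], exposure = ex, dRFU = d,
      sd = sqrt((stats::var(a) + stats::var(b)) / 2), p = p)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$exposure), ]
  out$p <- stats::p.adjust(out$p, method = adjust)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Two-ligand synergy statistic
#'
#' S = dRFU_ternary - (dRFU_ligand1 + dRFU_ligand2), per peptide and
#' exposure, for peptides measured in all four states. S > 0 indicates a
#' super-additive (synergistic) conformational response to the two
#' ligands bound simultaneously. The variance of S is propagated across
#' the four state means, Var(S) = (s_t^2 + s_1^2 + s_2^2 + s_a^2)/n with
#' a Welch-Satterthwaite df; a one-sided p for S > 0 is reported
#' alongside the two-sided p.
#'
#' @param hdx an [HDXDataset-class] containing states `ref`, `state1`,
#'   `state2` and `ternary`.
#' @param state1,state2,ternary,ref state labels (defaults `"S1P"`,
#'   `"PIP2"`, `"ternary"`, `"apo"`).
#' @param alpha significance threshold applied to the one-sided p.
#' @return data.frame with columns `start`, `end`, `exposure`, `S`, `se`,
#'   `df`, `p_two`, `p_greater`, `significant`. Peptides missing a state
#'   are skipped with a message.
#' @export
synergy <- function(hdx, state1 = "S1P", state2 = "PIP2",
                    ternary = "ternary", ref = "apo", alpha = 0.05) {
  stopifnot(is(hdx, "HDXDataset"))
  u <- hdx@uptake
  states <- c(ref, state1, state2, ternary)
  missing <- setdiff(states, unique(u$state))
  if (length(missing)) stop("missing state(s): ", paste(missing, collapse = ", "))
  pep <- hdx@peptides[hdx@peptides$nmax > 0, , drop = FALSE]
  has <- Reduce(`&`, lapply(states, function(s)
    .pepKey(pep) %in% .pepKey(u[u$state == s, ])))
  if (any(!has))
    message("skipping ", sum(!has), " peptide(s) lacking all four states")
  pep <- pep[has, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pep))) for (ex in hdx@exposures) {
    g <- lapply(states, function(s)
      .rfuReplicates(u, pep$start[i], pep$end[i], s, ex, pep$nmax[i]))
    if (any(lengths(g) < 2)) next
    m <- vapply(g, mean, 0)
    v <- vapply(g, stats::var, 0)
    n <- lengths(g)
    S <- m[4] - m[2] - m[3] + m[1]   # ternary - s1 - s2 + apo
    varS <- sum(v / n)
    se <- sqrt(varS)
    df <- if (varS > 0) varS^2 / sum((v / n)^2 / (n - 1)) else NA_real_
    tt <- if (se > 0) S / se else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      start = pep$start[i], end = pep$end[i], exposure = ex, S = S,
      se = se, df = df,
      p_two = if (is.na(tt)) NA_real_ else 2 * stats::pt(-abs(tt), df),
      p_greater = if (is.na(tt)) NA_real_ else stats::pt(tt, df,
                                                         lower.tail = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$exposure), ]
  out$significant <- !is.na(out$p_greater) & out$p_greater < alpha
  rownames(out) <- NULL
  out
}

#' Sequence coverage and redundancy of a peptide map
#'
#' Coverage is the percentage of residues covered by at least one
#' peptide; redundancy is the summed peptide length over the number of
#' covered residues.
#'
#' @param peptides data.frame with columns `start`, `end` (1-based,
#'   inclusive).
#' @param seqLength protein length in residues.
#' @return list with `nPeptides`, `coverage` (percent), `redundancy`.
#' @examples
#' coverageStats(data.frame(start = c(1, 41), end = c(50, 73)), 100)
#' @export
coverageStats <- function(peptides, seqLength) {
  stopifnot(is.data.frame(peptides), seqLength >= 1)
  if (!nrow(peptides))
    return(list(nPeptides = 0L, coverage = 0, redundancy = NA_real_))
  if (any(peptides$start < 1) || any(peptides$end > seqLength) ||
      any(peptides$end < peptides$start))
    stop("peptide out of sequence bounds")
  covered <- rep(FALSE, seqLength)
  for (i in seq_len(nrow(peptides)))
    covered[peptides$start[i]:peptides$end[i]] <- TRUE
  nCov <- sum(covered)
  list(nPeptides = nrow(peptides),
       coverage = 100 * nCov / seqLength,
       redundancy = sum(peptides$end - peptides$start + 1) / nCov)
}

#' Project peptide-level differential values onto residues
#'
#' Aggregates, per residue, the values of all covering peptides: the mean
#' (default) or, in `min_length` mode, the value of the shortest covering
#' peptide (sharper localization). Residues covered by no peptide are NA.
#'
#' @param differential data.frame with columns `start`, `end` and a value
#'   column (see `value`), typically one exposure slice of [deltaRfu()]
#'   output.
#' @param seqLength protein length; defaults to the largest `end`.
#' @param mode `"mean"` or `"min_length"`.
#' @param value name of the value column (default `"dRFU"`).
#' @return numeric vector of length `seqLength` (NA = uncovered).
#' @export
projectToResidues <- function(differential, seqLength = max(differential$end),
                              mode = c("mean", "min_length"),
                              value = "dRFU") {
  mode <- match.arg(mode)
  stopifnot(nrow(differential) > 0, value %in% names(differential))
  track <- rep(NA_real_, seqLength)
  if (mode == "mean") {
    acc <- rep(0, seqLength); cnt <- rep(0L, seqLength)
    for (i in seq_len(nrow(differential))) {
      r <- differential$start[i]:differential$end[i]
      acc[r] <- acc[r] + differential[[value]][i]
      cnt[r] <- cnt[r] + 1L
    }
    track[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  } else {
    len <- rep(Inf, seqLength)
    for (i in seq_len(nrow(differential))) {
      r <- differential$start[i]:differential$end[i]
      li <- differential$end[i] - differential$start[i] + 1
      upd <- li < len[r]
      track[r][upd] <- differential[[value]][i]
      len[r][upd] <- li
    }
  }
  track
}

#' Write a residue track into the B-factor column of a PDB
#'
#' Values are clamped to \[-9.99, 99.99\] (fixed-width field limits);
#' residues missing from the track get B = 0.00 and occupancy 0 so that
#' they can be masked in visualization.
#'
#' @param pdbFile input PDB path.
#' @param track numeric residue track indexed by residue number (as from
#'   [projectToResidues()]).
#' @param outFile output PDB path.
#' @return invisibly, the output path.
#' @export
writeResidueTrackPDB <- function(pdbFile, track, outFile) {
  pdb <- bio3d::read.pdb(pdbFile)
  resno <- pdb$atom$resno
  val <- rep(NA_real_, length(resno))
  ok <- resno >= 1 & resno <= length(track)
  val[ok] <- track[resno[ok]]
  miss <- is.na(val)
  b <- pmin(pmax(ifelse(miss, 0, val), -9.99), 99.99)
  occ <- ifelse(miss, 0, 1)
  bio3d::write.pdb(pdb, b = round(b, 2), o = occ, file = outFile)
  invisible(outFile)
}
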