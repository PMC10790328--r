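# Native-MS peak processing: centroiding, charge-series deconvolution,
# lipid-adduct assignment, mole fractions, competition and mixture tests.

#' Construct a PeakList
#'
#' @param mz numeric m/z values in Thomson (strictly increasing; the input
#'   is sorted).
#' @param intensity numeric intensities, >= 0, parallel to `mz`.
#' @param label optional character label.
#' @param replicate optional replicate identifier.
#' @return a [PeakList-class].
#' @export
peakList <- function(mz, intensity, label = NULL, replicate = NULL) {
  ord <- order(mz)
  new("PeakList", mz = as.numeric(mz[ord]),
      intensity = as.numeric(intensity[ord]),
      metadata = list(label = label, replicate = replicate))
}

#' Pick centroids from a profile spectrum
#'
#' Local maxima above a noise floor estimated from the median absolute
#' deviation of the trace; apexes closer than `minSpacing` are merged and
#' each centroid is the intensity-weighted mean m/z over its local window.
#' An all-zero spectrum yields an empty PeakList, not an error.
#'
#' @param profile a [PeakList-class] holding the profile trace.
#' @param minSnr signal-to-noise multiple of the MAD-based noise estimate
#'   a local maximum must exceed (default 3).
#' @param minSpacing minimum centroid spacing in Thomson (default 5).
#' @return a [PeakList-class] of centroids; centroid intensity is the apex
#'   intensity of the window.
#' @export
pickPeaks <- function(profile, minSnr = 3, minSpacing = 5) {
  stopifnot(is(profile, "PeakList"))
  mz <- profile@mz
  y <- profile@intensity
  if (!length(mz)) stop("profile is empty")
  noise <- stats::mad(y)
  floor <- stats::median(y) + minSnr * max(noise, .Machine$double.eps)
  if (all(y == 0)) return(peakList(numeric(), numeric(),
                                   label = profile@metadata$label))
  n <- length(y)
  isMax <- y > floor &
    y >= c(-Inf, y[-n]) &
    y >= c(y[-1], -Inf)
  apexes <- which(isMax)
  if (!length(apexes)) return(peakList(numeric(), numeric(),
                                       label = profile@metadata$label))
  keep <- integer()
  for (i in apexes[order(y[apexes], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(mz[i] - mz[keep]) >= minSpacing))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  base <- stats::median(y)   # baseline level, removed before weighting
  cen <- vapply(keep, function(i) {
    win <- which(abs(mz - mz[i]) <= minSpacing / 2)
    w <- pmax(y[win] - base, 0)
    c(sum(mz[win] * w) / sum(w), max(y[win]))
  }, numeric(2))
  peakList(cen[1, ], cen[2, ], label = profile@metadata$label,
           replicate = profile@metadata$replicate)
}

#' Deconvolve neutral masses from a charge series
#'
#' Exhaustive scan over candidate neutral masses implied by every
#' (peak, charge) pair under the positive-ion convention
#' m/z = (M + z * 1.00728) / z. Each candidate is scored by the number of
#' matched charge states weighted by intensity; matched candidates are
#' refined by an intensity-weighted mean and deduplicated within
#' `massWindow`. Candidates explaining fewer than 3 charge states are
#' dropped; if none remain the result is an empty list carrying a
#' `diagnostic` attribute.
#'
#' @param peaks a centroided [PeakList-class] (>= 3 peaks).
#' @param massWindow neutral-mass tolerance in Da for matching and for
#'   merging duplicate candidates (default 10).
#' @param zRange integer(2) charge-state search range, within \[5, 30\]
#'   (default c(10, 25)).
#' @param top number of ranked assignments to return (default 5).
#' @return list of [ChargeSeries-class], ranked by score (best first).
#' @examples
#' mp <- 1.00728
#' z <- 14:17
#' pl <- peakList((58000 + z * mp) / z, rep(100, 4))
#' deconvolveMass(pl, zRange = c(12, 20))[[1]]
#' @export
deconvolveMass <- function(peaks, massWindow = 10, zRange = c(10, 25),
                           top = 5L) {
  stopifnot(is(peaks, "PeakList"))
  if (length(peaks@mz) < 3) stop("need at least 3 peaks to deconvolve")
  if (zRange[1] < 5 || zRange[2] > 30 || zRange[1] >= zRange[2])
    stop("zRange must lie within [5, 30]")
  mp <- .PROTON_MASS
  zs <- seq(zRange[1], zRange[2])
  mz <- peaks@mz
  y <- peaks@intensity
  cand <- as.vector(outer(mz - mp, zs))          # candidate neutral masses
  cand <- cand[cand > 0]
  series <- list()
  for (M in cand) {
    expected <- (M + zs * mp) / zs
    idx <- vapply(seq_along(zs), function(j) {
      d <- abs(mz - expected[j])
      i <- which.min(d)
      if (d[i] * zs[j] <= massWindow) i else NA_integer_
    }, 0L)
    hit <- which(!is.na(idx))
    if (length(hit) < 3) next
    # one peak may satisfy only one charge state
    dup <- duplicated(idx[hit])
    hit <- hit[!dup]
    if (length(hit) < 3) next
    pk <- idx[hit]
    w <- y[pk]
    Mz <- zs[hit] * (mz[pk] - mp)
    mRef <- sum(Mz * w) / sum(w)
    # robust second pass: centroids distorted by overlapping satellite
    # peaks are trimmed before the final weighted mean
    dev <- Mz - stats::median(Mz)
    good <- abs(dev) <= max(3 * stats::mad(Mz), 0.3)
    if (sum(good) >= 3)
      mRef <- sum(Mz[good] * w[good]) / sum(w[good])
    resid <- Mz - mRef
    series[[length(series) + 1]] <- new("ChargeSeries", mass = mRef,
      charges = as.integer(zs[hit]), peakIndex = as.integer(pk),
      residuals = resid, score = length(hit) * sum(w))
  }
  if (!length(series)) {
    out <- list()
    attr(out, "diagnostic") <- "no candidate mass matched >= 3 charge states"
    return(out)
  }
  masses <- vapply(series, function(s) s@mass, 0)
  scores <- vapply(series, function(s) s@score, 0)
  ord <- order(scores, decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    if (!length(kept) ||
        all(abs(masses[i] - vapply(kept, function(s) s@mass, 0)) > massWindow))
      kept[[length(kept) + 1]] <- series[[i]]
    if (length(kept) >= top) break
  }
  kept
}

#' Assign lipid-adduct ladders to peaks above a base charge series
#'
#' For each charge state of the base (apo) assignment, peaks are converted
#' to neutral mass and matched against M0 + k * lipid mass for every
#' candidate lipid and stoichiometry k = 0..`maxK`. Each peak is assigned
#' to at most one (lipid, k), ties broken by smallest absolute residual;
#' peaks matching two candidates within the tolerance are flagged
#' ambiguous rather than silently resolved.
#'
#' @param peaks a centroided [PeakList-class].
#' @param base a [ChargeSeries-class] for the apo protein.
#' @param candidates data.frame with columns `name` and `average_mass`
#'   (e.g. rows of [lipidTable()]).
#' @param tol neutral-mass tolerance in Da (default 3).
#' @param maxK maximum stoichiometry (default 4).
#' @return an [AdductAssignment-class].
#' @export
assignLipidAdducts <- function(peaks, base, candidates, tol = 3, maxK = 4L) {
  stopifnot(is(peaks, "PeakList"), is(base, "ChargeSeries"),
            all(c("name", "average_mass") %in% names(candidates)))
  mp <- .PROTON_MASS
  M0 <- base@mass
  ladder <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    data.frame(lipid = candidates$name[i], k = seq_len(maxK),
               mass = M0 + seq_len(maxK) * candidates$average_mass[i])
  }))
  ladder <- rbind(data.frame(lipid = NA_character_, k = 0L, mass = M0), ladder)
  rows <- list()
  for (z in base@charges) {
    neutral <- z * (peaks@mz - mp)
    inRange <- which(neutral >= M0 - tol &
                     neutral <= max(ladder$mass) + tol)
    for (i in inRange) {
      d <- neutral[i] - ladder$mass
      hits <- which(abs(d) <= tol)
      if (!length(hits)) next
      bestHit <- hits[which.min(abs(d[hits]))]
      rows[[length(rows) + 1]] <- data.frame(
        charge = z, peakIndex = i, lipid = ladder$lipid[bestHit],
        k = ladder$k[bestHit], mz = peaks@mz[i],
        intensity = peaks@intensity[i], residual = d[bestHit],
        ambiguous = length(unique(ladder$lipid[hits])) > 1)
    }
  }
  asn <- if (length(rows)) do.call(rbind, rows) else
    data.frame(charge = integer(), peakIndex = integer(),
               lipid = character(), k = integer(), mz = numeric(),
               intensity = numeric(), residual = numeric(),
               ambiguous = logical())
  new("AdductAssignment", baseMass = M0, assignments = asn,
      maxStoichiometry = as.integer(maxK))
}

#' Bound-state mole fractions from an adduct assignment
#'
#' x_k = I_k / sum_j I_j, the intensity of the k-lipid-bound species over
#' the total intensity of all observed species. The default aggregates
#' intensities summed across charge states; `per_charge` computes one row
#' per charge state (as when a single charge state is read out).
#'
#' @param adducts an [AdductAssignment-class].
#' @param aggregate `"summed"` (default) or `"per_charge"`.
#' @return data.frame with columns `charge` (NA when summed) and
#'   `x0`..`x<maxK>`; each row sums to 1.
#' @export
moleFractions <- function(adducts, aggregate = c("summed", "per_charge")) {
  aggregate <- match.arg(aggregate)
  a <- adducts@assignments
  if (!nrow(a)) stop("no assigned species")
  kMax <- adducts@maxStoichiometry
  rowFor <- function(sub, charge) {
    tot <- sum(sub$intensity)
    if (tot <= 0) stop("zero total intensity")
    x <- vapply(0:kMax, function(k) sum(sub$intensity[sub$k == k]) / tot, 0)
    out <- data.frame(charge = charge, t(x))
    names(out) <- c("charge", paste0("x", 0:kMax))
    out
  }
  if (aggregate == "summed") return(rowFor(a, NA_integer_))
  do.call(rbind, lapply(split(a, a$charge),
                        function(s) rowFor(s, s$charge[1])))
}

.stars <- function(p) {
  ifelse(is.na(p), "na",
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

# Welch two-tailed unpaired t-test that degrades gracefully: returns NA p
# with a warning when both groups have zero variance (degenerate), p = 1
# when the groups are identical with spread.
.welch <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("degenerate zero within-group variance; test skipped")
    return(list(p = NA_real_, t = NA_real_, df = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(p = ht$p.value, t = unname(ht$statistic), df = unname(ht$parameter))
}

#' Compare single-state bound intensities across competing lipids
#'
#' Replicate intensities of the singly bound species for each lipid in an
#' equimolar competition are summarized (mean, SD), ranked, and compared
#' pairwise by two-tailed unpaired (Welch) t-tests with significance
#' stars at the 0.05 / 0.01 / 0.001 / 0.0001 thresholds.
#'
#' @param intensities named list: one numeric replicate vector per lipid
#'   (>= 2 lipids, >= 2 replicates each, equal replicate structure).
#' @return list with `summary` (lipid, mean, sd, n, rank) and `pairwise`
#'   (lipid1, lipid2, p, stars).
#' @export
competitionCompare <- function(intensities) {
  stopifnot(is.list(intensities), length(intensities) >= 2)
  ns <- lengths(intensities)
  if (any(ns < 2)) stop("need >= 2 replicates per lipid")
  if (length(unique(ns)) != 1)
    stop("unequal replicate labels across lipids")
  nms <- names(intensities)
  means <- vapply(intensities, mean, 0)
  summary <- data.frame(lipid = nms, mean = means,
                        sd = vapply(intensities, stats::sd, 0),
                        n = as.integer(ns),
                        rank = rank(-means, ties.method = "min"),
                        row.names = NULL)
  prs <- utils::combn(nms, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    a <- intensities[[prs[1, j]]]
    b <- intensities[[prs[2, j]]]
    p <- if (identical(a, b) && stats::sd(a) == 0) 1 else .welch(a, b)$p
    if (identical(unname(a), unname(b))) p <- 1  # identical sets: no difference
    data.frame(lipid1 = prs[1, j], lipid2 = prs[2, j], p = p,
               stars = .stars(p))
  }))
  list(summary = summary[order(summary$rank), ], pairwise = pairwise)
}

#' Bound/apo intensity ratios for two co-analyzed proteins
#'
#' For a mixture of two proteins titrated with one ligand, computes per
#' replicate the ratio of the singly bound to the apo peak intensity for
#' each protein, and compares the two proteins' ratios by a two-tailed
#' unpaired (Welch) t-test. Zero within-group variance is flagged as
#' degenerate and the test skipped with a warning.
#'
#' @param ratios data.frame with columns `protein`, `replicate`, `apo`,
#'   `bound` (intensities); exactly two proteins.
#' @return list with `summary` (protein, meanRatio, sd, n), `p`, `stars`.
#' @export
mixtureBoundRatio <- function(ratios) {
  need <- c("protein", "replicate", "apo", "bound")
  stopifnot(is.data.frame(ratios), all(need %in% names(ratios)))
  prots <- unique(ratios$protein)
  if (length(prots) != 2) stop("exactly two proteins required")
  if (any(is.na(ratios$apo)) || any(ratios$apo <= 0))
    stop("missing apo peak intensity for at least one protein/replicate")
  ratios$ratio <- ratios$bound / ratios$apo
  grp <- split(ratios$ratio, ratios$protein)[prots]
  res <- .welch(grp[[1]], grp[[2]])
  list(summary = data.frame(protein = prots,
                            meanRatio = vapply(grp, mean, 0),
                            sd = vapply(grp, stats::sd, 0),
                            n = lengths(grp), row.names = NULL),
       p = res$p, stars = .stars(res$p))
}
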