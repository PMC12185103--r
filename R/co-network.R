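# Interregional cytochrome-oxidase covariance: replicate averaging,
# standards normalisation, Pearson correlation over all region pairs,
# FDR-tiered edge selection, Fisher-z group comparison, and graph export.

#' Average optical-density replicates into a subject-by-region table
#'
#' Arithmetic mean per subject and region across the 3-6 replicate readings
#' and both hemispheres. Subjects with no reading for a region get NA
#' (logged); such subjects are dropped pairwise in the correlation stage.
#'
#' @param readings data.frame with columns `subject`, `group`, `region`,
#'   `od` (and optionally `hemisphere`, `reading_index`, ignored beyond
#'   averaging).
#' @param regions region order for the output columns (default the canonical
#'   14-region panel restricted to those present).
#' @return A [RegionTable-class].
#' @export
averageReplicates <- function(readings, regions = NULL) {
  stopifnot(all(c("subject", "group", "region", "od") %in% names(readings)))
  if (is.null(regions)) {
    regions <- intersect(canonicalRegions, unique(readings$region))
    if (length(regions) == 0) regions <- sort(unique(readings$region))
  }
  subjects <- unique(readings$subject)
  m <- matrix(NA_real_, length(subjects), length(regions),
              dimnames = list(subjects, regions))
  agg <- stats::aggregate(od ~ subject + region, readings, mean)
  idx <- cbind(match(agg$subject, subjects), match(agg$region, regions))
  ok <- !is.na(idx[, 2])
  m[idx[ok, , drop = FALSE]] <- agg$od[ok]
  if (any(is.na(m))) {
    message(sprintf("averageReplicates: %d missing subject x region cells",
                    sum(is.na(m))))
  }
  grp <- readings$group[match(subjects, readings$subject)]
  RegionTable(m, grp)
}

#' Normalise optical densities to a batch standards curve
#'
#' Fits OD against section thickness for each batch's homogenate standards
#' (20/40/60/80 um) and divides each raw OD by its batch slope, expressing
#' activity per um of tissue. Identical batches make this a common
#' rescaling, which leaves every Pearson correlation unchanged.
#'
#' @param raw data.frame with columns `batch`, `od` (plus any id columns,
#'   preserved).
#' @param standards data.frame with columns `batch`, `thickness_um`, `od`.
#' @return `raw` with an added `activity` column.
#' @export
normalizeToStandards <- function(raw, standards) {
  stopifnot(all(c("batch", "od") %in% names(raw)),
            all(c("batch", "thickness_um", "od") %in% names(standards)))
  slopes <- vapply(split(standards, standards$batch), function(s) {
    if (length(unique(s$thickness_um)) < 2) {
      stop("normalizeToStandards: degenerate standards (constant thickness)")
    }
    stats::coef(stats::lm(od ~ thickness_um, data = s))[["thickness_um"]]
  }, numeric(1))
  if (any(slopes == 0)) {
    stop("normalizeToStandards: zero-slope standards curve")
  }
  raw$activity <- raw$od / slopes[as.character(raw$batch)]
  raw
}

#' Pearson correlation matrix of one group's region table
#'
#' Pearson r and two-sided p for every unordered region pair within one
#' group, with pairwise-complete subjects. Adds the two significance tiers
#' of the network figure: uncorrected p < 0.05 and Benjamini-Hochberg FDR
#' at `q` over the group's full set of pairs.
#'
#' @param table a [RegionTable-class].
#' @param group group label to select.
#' @param q FDR level (default 0.01).
#' @return data.frame (EdgeSet): `region1`, `region2`, `r`, `n`, `p`,
#'   `sig_p05`, `sig_fdr`, `group`.
#' @export
correlationMatrix <- function(table, group, q = 0.01) {
  stopifnot(is(table, "RegionTable"))
  v <- table@values[table@group == group, , drop = FALSE]
  if (nrow(v) < 4) stop("correlationMatrix: need at least 4 subjects")
  regions <- colnames(v)
  pairs <- utils::combn(length(regions), 2)
  r <- numeric(ncol(pairs)); n <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- v[, pairs[1, k]]; b <- v[, pairs[2, k]]
    ok <- !is.na(a) & !is.na(b)
    n[k] <- sum(ok)
    r[k] <- if (n[k] >= 3) stats::cor(a[ok], b[ok]) else NA_real_
  }
  # two-sided p from the exact t transform of r
  tt <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  edges <- data.frame(
    region1 = regions[pairs[1, ]], region2 = regions[pairs[2, ]],
    r = r, n = n, p = p,
    sig_p05 = !is.na(p) & p < 0.05,
    sig_fdr = fdrSelect(p, q = q),
    group = group
  )
  edges
}

#' Benjamini-Hochberg selection at FDR level q
#'
#' @param pvalues vector of p-values (NAs never selected).
#' @param q FDR level (default 0.01).
#' @return logical vector: selected by the BH step-up procedure.
#' @export
fdrSelect <- function(pvalues, q = 0.01) {
  adj <- stats::p.adjust(pvalues, method = "BH")
  !is.na(adj) & adj <= q
}

#' Fisher-z comparison of two correlations
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), two-sided normal p.
#'
#' @param r1,r2 correlations, |r| < 1.
#' @param n1,n2 sample sizes, >= 4.
#' @return list: `z`, `p`.
#' @export
fisherZCompare <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("fisherZCompare: |r| must be < 1 (atanh diverges)")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pooled two-proportion z-test
#'
#' z = (k1/n1 - k2/n2) / sqrt(p(1-p)(1/n1 + 1/n2)) with p the pooled
#' proportion; two-sided normal p.
#'
#' @param k1,k2 successes.
#' @param n1,n2 trials.
#' @return list: `z`, `p`.
#' @export
proportionTest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0)
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0) {
    stop("proportionTest: counts must satisfy 0 <= k <= n")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Build the covariance network graph
#'
#' Nodes are all regions of the edge set; edges are the pairs significant
#' at uncorrected p < 0.05, carrying `r`, `p` and a `tier` attribute
#' ("fdr" for edges that also survive the FDR threshold, else "p05"; the
#' FDR tier is nested inside the p < 0.05 tier).
#'
#' @param edges a [correlationMatrix()] data.frame.
#' @return an [igraph::igraph] object.
#' @export
buildGraph <- function(edges) {
  nodes <- sort(unique(c(edges$region1, edges$region2)))
  sig <- edges[!is.na(edges$p) & edges$sig_p05, , drop = FALSE]
  el <- data.frame(
    from = sig$region1, to = sig$region2,
    r = sig$r, p = sig$p,
    tier = ifelse(sig$sig_fdr, "fdr", "p05")
  )
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Cross-group edge comparison table
#'
#' Fisher-z comparison of each region pair's correlation between two groups.
#'
#' @param edgesA,edgesB [correlationMatrix()] outputs for the two groups.
#' @return data.frame: `region1`, `region2`, `r_a`, `r_b`, `fisher_z`, `p`.
#' @export
compareGroups <- function(edgesA, edgesB) {
  key <- function(e) paste(e$region1, e$region2)
  stopifnot(identical(key(edgesA), key(edgesB)))
  res <- mapply(function(r1, n1, r2, n2) {
    if (any(is.na(c(r1, r2))) || abs(r1) >= 1 || abs(r2) >= 1 ||
        n1 < 4 || n2 < 4) {
      c(NA_real_, NA_real_)
    } else {
      fz <- fisherZCompare(r1, n1, r2, n2)
      c(fz$z, fz$p)
    }
  }, edgesA$r, edgesA$n, edgesB$r, edgesB$n)
  data.frame(
    region1 = edgesA$region1, region2 = edgesA$region2,
    r_a = edgesA$r, r_b = edgesB$r,
    fisher_z = res[1, ], p = res[2, ]
  )
}
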