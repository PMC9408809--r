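#' Pool biomarker maps by myocardial region
#'
#' Every labeled myocardial voxel contributes its map values to exactly
#' one region; voxels excluded by `valid` (e.g. MD-rejected or invalid
#' tensor fits) and non-finite values are dropped.
#'
#' @param maps Named list of [volume3d()] maps (or arrays) on the label
#'   grid.
#' @param labels A [label_map()].
#' @param subject_id Subject identifier attached to every row.
#' @param valid Optional logical array of voxels to keep.
#' @return A data.frame with columns `subject`, `region` (factor
#'   remote/border/infarct), `quantity`, `value`.
#' @export
pool_by_region <- function(maps, labels, subject_id = "S1", valid = NULL) {
  stopifnot(inherits(labels, "label_map"), length(maps) > 0,
            !is.null(names(maps)))
  d3 <- dim(labels$data)
  arrs <- lapply(maps, function(m) if (inherits(m, "volume3d")) m$data else m)
  for (a in arrs) if (!identical(dim(a), d3)) stop("map/label grid mismatch")
  keep <- labels$data > 0L
  if (!is.null(valid)) {
    if (!identical(dim(valid), d3)) stop("valid mask grid mismatch")
    keep <- keep & valid
  }
  idx <- which(keep)
  reg <- factor(region_names[labels$data[idx]], levels = region_names)
  out <- do.call(rbind, lapply(names(arrs), function(nm) {
    v <- arrs[[nm]][idx]
    ok <- is.finite(v)
    data.frame(subject = subject_id, region = reg[ok], quantity = nm,
               value = v[ok], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Anderson-Darling normality test
#'
#' Case-3 Anderson-Darling test (mean and variance estimated from the
#' sample) with the standard small-sample correction and p-value
#' approximation.
#'
#' @param sample Numeric vector with at least 8 finite, non-constant
#'   values.
#' @return List with the statistic `A2` and the p-value `p`.
#' @export
anderson_darling <- function(sample) {
  x <- sample[is.finite(sample)]
  if (length(x) < 8L) stop("Anderson-Darling test requires n >= 8")
  if (sd(x) == 0) stop("constant sample (zero variance)")
  res <- nortest::ad.test(x)
  list(A2 = unname(res$statistic), p = res$p.value)
}

# Tie-corrected two-group Kruskal-Wallis H statistic (chi-square form).
kw_h_statistic <- function(a, b) {
  unname(kruskal.test(list(a, b))$statistic)
}

#' Pairwise Kruskal-Wallis tests with Bonferroni adjustment
#'
#' For each pair of regions, the two-group tie-corrected Kruskal-Wallis H
#' statistic is compared against chi-square with 1 df; p-values are
#' multiplied by the number of pairs (3 for the three myocardial regions)
#' and capped at 1.
#'
#' @param groups Named list of numeric samples (each pair needs >= 2
#'   observations per group).
#' @param alpha Significance level (the convention used throughout is
#'   0.01).
#' @return Data.frame with columns `group1`, `group2`, `H`, `p`, `p_adj`,
#'   `significant`.
#' @export
kruskal_wallis_pairwise <- function(groups, alpha = 0.01) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  for (nm in names(groups)) {
    groups[[nm]] <- groups[[nm]][is.finite(groups[[nm]])]
    if (length(groups[[nm]]) < 2L) stop("group '", nm, "' has fewer than 2 observations")
  }
  prs <- utils::combn(names(groups), 2L)
  m <- ncol(prs)
  rows <- lapply(seq_len(m), function(j) {
    a <- groups[[prs[1L, j]]]; b <- groups[[prs[2L, j]]]
    if (length(unique(c(a, b))) == 1L) {
      h <- 0; p <- 1
    } else {
      kt <- kruskal.test(list(a, b))
      h <- unname(kt$statistic); p <- kt$p.value
    }
    data.frame(group1 = prs[1L, j], group2 = prs[2L, j], H = h, p = p,
               p_adj = min(1, m * p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out
}

#' Regional summary statistics
#'
#' Mean, median, and first/third quartiles per region and quantity.
#' Quartiles use the linear-interpolation convention between order
#' statistics (R quantile type 7).
#'
#' @param pooled Data.frame from [pool_by_region()] (possibly several
#'   subjects concatenated).
#' @return Data.frame with columns `quantity`, `region`, `mean`, `median`,
#'   `q1`, `q3`, `n`.
#' @export
summarize_regions <- function(pooled) {
  stopifnot(all(c("region", "quantity", "value") %in% names(pooled)))
  if (nrow(pooled) == 0L) stop("empty sample")
  sp <- split(pooled$value, list(pooled$quantity, pooled$region), drop = TRUE)
  rows <- lapply(names(sp), function(key) {
    v <- sp[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    q <- unname(quantile(v, c(0.25, 0.75), type = 7))
    data.frame(quantity = parts[1L], region = parts[2L], mean = mean(v),
               median = median(v), q1 = q[1L], q3 = q[2L], n = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$region <- factor(out$region, levels = region_names)
  out[order(out$quantity, out$region), ]
}

#' Percent change in medians between two samples
#'
#' `100 * (median(a) - median(reference)) / median(reference)`, sign
#' preserved (decreases, e.g. in FA, come out negative).
#'
#' @param a Numeric sample of interest.
#' @param reference Numeric reference sample (nonzero median).
#' @return Percent change (scalar).
#' @export
percent_change_of_medians <- function(a, reference) {
  mref <- median(reference[is.finite(reference)])
  if (mref == 0) stop("zero reference median")
  100 * (median(a[is.finite(a)]) - mref) / mref
}
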