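# Quantitative comparison of automatic vs ground-truth segmentations:
# Dice overlap, compartment volumes and mean PDFF, and the paired Wilcoxon
# signed-rank test.

#' Dice overlap coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`.  Two empty masks are defined to agree perfectly
#' (Dice 1, with a warning).
#'
#' @param a,b logical arrays (or `volume3d`s whose nonzero voxels form the
#'   mask) on identical grids.
#' @return Dice value in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "volume3d")) {
    if (inherits(b, "volume3d") && !same_geometry(a, b))
      stop("mask grids do not match")
    a <- a$data != 0
  }
  if (inherits(b, "volume3d")) b <- b$data != 0
  if (!identical(dim(a), dim(b))) stop("mask grids do not match")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (with their count reported); ties get
#' midranks.  For n <= `exact_max` pairs the two-sided p-value is exact,
#' computed from the full distribution of the signed-rank sum over all 2^n
#' equiprobable sign assignments (a dynamic program equivalent to complete
#' enumeration, valid with midranks); beyond that a normal approximation
#' with tie correction is used.
#'
#' @param x,y paired numeric samples of equal length.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (signed-rank sum W+ of positive
#'   differences), `p_value` (two-sided), `n_used`, `n_zero`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (!length(x)) stop("empty samples")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_used = 0, n_zero = n_zero,
                exact = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of W+ over all sign patterns; doubled midranks are integers
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    dist <- numeric(tot + 1)
    dist[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(tot + 1 - ri)])
      dist <- dist + shifted
    }
    probs <- dist / 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_lo <- sum(probs[seq_len(w2 + 1)])
    p_hi <- sum(probs[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = w_plus, p_value = p, n_used = n, n_zero = n_zero,
       exact = exact)
}

#' Per-compartment comparison of two segmentations
#'
#' For each of the six compartments: Dice overlap, volumes (voxel count
#' times voxel volume, cm^3), mean PDFF over each mask, and the absolute
#' PDFF difference.  Compartments missing from the ground truth are flagged
#' by `NA` rows rather than silently zeroed.
#'
#' @param labels_gt,labels_as ground-truth and automatic `label_volume`s.
#' @param pdff PDFF map (`volume3d`, percent) on the same grid.
#' @return data.frame with one row per compartment.
#' @export
compartment_stats <- function(labels_gt, labels_as, pdff) {
  if (!same_geometry(labels_gt, labels_as) || !same_geometry(labels_gt, pdff))
    stop("volumes do not share a common grid")
  vox_cm3 <- prod(labels_gt$spacing) / 1000
  rows <- lapply(1:6, function(cc) {
    gt <- labels_gt$data == cc
    as_ <- labels_as$data == cc
    if (!any(gt)) {
      warning("compartment ", cc, " missing from ground truth; row flagged NA")
      return(data.frame(compartment = cc, name = COMPARTMENT_NAMES[cc],
                        dice = NA_real_, gt_volume_cm3 = NA_real_,
                        as_volume_cm3 = sum(as_) * vox_cm3,
                        gt_pdff = NA_real_, as_pdff = NA_real_,
                        delta_pdff = NA_real_))
    }
    data.frame(compartment = cc, name = COMPARTMENT_NAMES[cc],
               dice = dice_coefficient(gt, as_),
               gt_volume_cm3 = sum(gt) * vox_cm3,
               as_volume_cm3 = sum(as_) * vox_cm3,
               gt_pdff = mean(pdff$data[gt]),
               as_pdff = if (any(as_)) mean(pdff$data[as_]) else NA_real_,
               delta_pdff = if (any(as_)) abs(mean(pdff$data[as_]) - mean(pdff$data[gt])) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Cohort evaluation table in the style of the per-compartment report
#'
#' Aggregates per-observation [compartment_stats()] results: per compartment
#' the mean and SD of GT/AS PDFF and volume, the mean absolute PDFF
#' difference, the mean Dice, and paired Wilcoxon signed-rank p-values for
#' the AS-vs-GT PDFF and volume comparisons across observations.
#'
#' @param stats_list list of data.frames from [compartment_stats()], one per
#'   test observation.
#' @return data.frame with one row per compartment plus a cohort-average row.
#' @export
evaluate_cohort <- function(stats_list) {
  if (!length(stats_list)) stop("no observations to evaluate")
  all <- do.call(rbind, Map(function(df, i) transform(df, obs = i),
                            stats_list, seq_along(stats_list)))
  rows <- lapply(1:6, function(cc) {
    s <- all[all$compartment == cc, ]
    p_ff <- wilcoxon_signed_rank(s$as_pdff, s$gt_pdff)$p_value
    p_vol <- wilcoxon_signed_rank(s$as_volume_cm3, s$gt_volume_cm3)$p_value
    data.frame(compartment = cc, name = COMPARTMENT_NAMES[cc],
               dice = mean(s$dice),
               gt_pdff = mean(s$gt_pdff), gt_pdff_sd = stats::sd(s$gt_pdff),
               as_pdff = mean(s$as_pdff), as_pdff_sd = stats::sd(s$as_pdff),
               # the compartment Delta fat fraction: difference of the
               # cohort means, as in the standard report table
               delta_pdff = abs(mean(s$as_pdff) - mean(s$gt_pdff)),
               p_pdff = p_ff,
               gt_volume_cm3 = mean(s$gt_volume_cm3),
               gt_volume_sd = stats::sd(s$gt_volume_cm3),
               as_volume_cm3 = mean(s$as_volume_cm3),
               as_volume_sd = stats::sd(s$as_volume_cm3),
               p_volume = p_vol)
  })
  out <- do.call(rbind, rows)
  avg <- out[1, ]
  avg$compartment <- NA
  avg$name <- "average"
  for (cl in setdiff(names(out), c("compartment", "name")))
    avg[[cl]] <- mean(out[[cl]])
  rbind(out, avg)
}
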