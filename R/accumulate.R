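#' Accumulate per-phase doses at the reference phase
#'
#' Pulls every phase dose back to T50 voxel centers through the
#' phantom's phase-to-reference deformation field (fixed-point inversion
#' of the stored field, trilinear interpolation) and sums.
#'
#' @param phase_doses named list (phase label -> dose array on that
#'   phase's geometry).
#' @param phantom a `phantom4d` providing the deformations.
#' @return accumulated dose array at T50.
#' @export
accumulate_dose <- function(phase_doses, phantom) {
  stopifnot(length(phase_doses) >= 1, !is.null(names(phase_doses)))
  missing <- setdiff(names(phase_doses), names(phantom$deformation_to_ref))
  if (length(missing))
    stop("missing deformation for phase(s): ", paste(missing, collapse = ", "))
  acc <- array(0, phantom$geom$dim)
  for (p in names(phase_doses))
    acc <- acc + warp_to_reference(phase_doses[[p]], phantom, p)
  acc
}

#' Cumulative dose-volume histogram
#'
#' Volume fraction of the structure receiving at least each dose level,
#' from the exact empirical dose distribution (no binning unless
#' `binwidth_gy` is given, in which case levels are a regular grid for
#' export).
#'
#' @param dose dose array.
#' @param mask logical structure mask (non-empty).
#' @param binwidth_gy optional bin width for a regular dose grid.
#' @return data frame `dose_gy`, `volume_pct`, non-increasing in dose,
#'   starting at 100% for dose 0.
#' @export
dvh <- function(dose, mask, binwidth_gy = NULL) {
  d <- dose[mask]
  if (length(d) == 0) stop("empty structure mask")
  if (is.null(binwidth_gy)) {
    lev <- sort(unique(c(0, d)))
  } else {
    lev <- seq(0, max(d) + binwidth_gy, by = binwidth_gy)
  }
  n <- length(d)
  # fraction of voxels with dose >= level
  vol <- (n - findInterval(lev - 1e-12, sort(d))) / n * 100
  data.frame(dose_gy = lev, volume_pct = vol)
}

#' Volume fraction at or above a dose
#' @param dose dose array.
#' @param mask logical mask.
#' @param dose_gy threshold dose.
#' @return percent of mask voxels with dose >= `dose_gy`.
#' @export
volume_at_least <- function(dose, mask, dose_gy) {
  100 * mean(dose[mask] >= dose_gy)
}

# largest dose d such that >= frac of the structure receives >= d
dose_at_volume <- function(d, frac = 0.95) {
  s <- sort(d)
  n <- length(d)
  k <- n - ceiling(frac * n) + 1
  s[max(k, 1)]
}

#' Dose metrics for target and organs at risk
#'
#' CTV D95 (largest dose received by at least 95% of the volume, exact
#' empirical), raw voxel Dmax/Dmin/Dmean, homogeneity index
#' HI = 100 * SD(CTV voxel doses) / prescription, lung V20 (percent of
#' lung at or above 20 Gy(RBE)), and mean/max/min for heart and cord.
#' Empty structures are reported as `NA`, not zero.
#'
#' @param dose accumulated dose array at the reference phase.
#' @param structures named list of reference-phase masks; `ctv` is
#'   required, `lung`, `heart`, `cord` optional.
#' @param prescription_gyrbe prescribed dose, Gy(RBE).
#' @return one-row data frame of metrics.
#' @export
dose_metrics <- function(dose, structures, prescription_gyrbe) {
  ctv <- structures$ctv
  if (is.null(ctv) || !any(ctv)) stop("CTV mask empty")
  d <- dose[ctv]
  oar <- function(name, fun) {
    m <- structures[[name]]
    if (is.null(m) || !any(m)) NA_real_ else fun(dose[m])
  }
  data.frame(
    D95 = dose_at_volume(d, 0.95),
    Dmax = max(d), Dmin = min(d), Dmean = mean(d),
    HI_pct = 100 * sd(d) / prescription_gyrbe,
    lung_V20_pct = if (is.null(structures$lung) || !any(structures$lung))
      NA_real_ else volume_at_least(dose, structures$lung, 20),
    lung_Dmean = oar("lung", mean),
    heart_Dmean = oar("heart", mean), heart_Dmax = oar("heart", max),
    heart_Dmin = oar("heart", min),
    cord_Dmean = oar("cord", mean), cord_Dmax = oar("cord", max),
    cord_Dmin = oar("cord", min))
}

#' Wilcoxon signed-rank test for paired metrics
#'
#' Two-sided p-value from the exact permutation null (all sign
#' assignments of the mid-ranked absolute differences) when n <= 15
#' after dropping zero differences, otherwise the normal approximation
#' with continuity and tie correction.  Identical samples are degenerate
#' and reported with p = 1.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list with `statistic` (V, sum of positive-difference ranks),
#'   `p.value`, `n` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p.value = 1, n = 0L,
                method = "degenerate (all differences zero)"))
  if (n < 5) stop("fewer than 5 non-zero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 15) {
    # exact: enumerate the 2^n sign assignments via the generating
    # polynomial over doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    cnt <- numeric(tot + 1)  # counts for doubled statistic 0..tot
    cnt[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), cnt[seq_len(tot + 1 - rr)])
      cnt <- cnt + shifted
    }
    v2 <- round(2 * V)
    p_ge <- sum(cnt[(v2 + 1):(tot + 1)]) / 2^n
    p_le <- sum(cnt[1:(v2 + 1)]) / 2^n
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact signed-rank (sign-pattern enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = V, p.value = p, n = n, method = method)
}
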