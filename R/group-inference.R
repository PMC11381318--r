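#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on
#' counts `a, b, c, d` laid out as rows = groups, columns =
#' responsive/unresponsive. Equals the closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; p from the chi-square
#' distribution with 1 df. Used for differences in proportions of
#' responding neurons among conditions.
#'
#' @param a,b First group: responsive, unresponsive counts.
#' @param c,d Second group: responsive, unresponsive counts.
#' @param correct Apply the Yates continuity correction (sensitivity
#'   checks only; default `FALSE`).
#' @return List of class `contingency_result`: `table`, `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(a, b, c, d, correct = FALSE) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be nonnegative integers")
  }
  tab <- matrix(cnt, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero margin")
  }
  N <- sum(tab)
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / prod(rowSums(tab), colSums(tab))
  structure(list(table = tab, chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "contingency_result")
}

#' Chi-square comparison of two response proportions
#'
#' Convenience front-end to [chi2_2x2()] for "x1 of n1 vs x2 of n2"
#' responsive-neuron comparisons.
#'
#' @param x1,n1 Responsive count and total in group 1.
#' @param x2,n2 Responsive count and total in group 2.
#' @param correct Yates correction flag.
#' @return A `contingency_result`.
#' @export
prop_chi2 <- function(x1, n1, x2, n2, correct = FALSE) {
  chi2_2x2(x1, n1 - x1, x2, n2 - x2, correct = correct)
}

#' Rank test between two magnitude samples
#'
#' Unpaired: rank-sum (Mann-Whitney) z over pooled ranks. Paired:
#' Wilcoxon signed-rank z on nonzero differences. Both use tie and
#' continuity corrections and a two-sided normal p. Within-neuron
#' interval contrasts are intrinsically paired and should use
#' `paired = TRUE`; between-region or between-subject contrasts are
#' unpaired.
#'
#' @param x,y Numeric samples (equal length when paired).
#' @param paired Logical.
#' @return List of class `rank_test_result`: `z`, `p`, `n1`, `n2` (or
#'   `n` pairs), `paired`.
#' @export
rank_compare <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      return(structure(list(z = 0, p = 1, n = 0, paired = TRUE),
                       class = "rank_test_result"))
    }
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    E <- n * (n + 1) / 4
    ties <- table(r)
    V <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (V <= 0) {
      z <- 0; p <- 1
    } else {
      dd <- W - E
      z <- sign(dd) * max(0, abs(dd) - 0.5) / sqrt(V)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    structure(list(z = z, p = p, n = n, paired = TRUE),
              class = "rank_test_result")
  } else {
    rz <- rank_z(x, y)
    structure(list(z = rz$z, p = rz$p, n1 = length(x), n2 = length(y),
                   paired = FALSE),
              class = "rank_test_result")
  }
}

#' Linear and Spearman trend of magnitude against MOT
#'
#' Least-squares regression of per-trial response magnitudes on movement
#' onset times, plus the Spearman rank correlation with its asymptotic p.
#'
#' @param magnitudes Per-trial percent magnitudes.
#' @param mots Per-trial MOTs (s).
#' @return List of class `trend_result`: `slope` (percent per second),
#'   `intercept`, `rho`, `p`, `n`, `slope_ci95`.
#' @export
mot_trend <- function(magnitudes, mots) {
  ok <- !is.na(magnitudes) & !is.na(mots)
  magnitudes <- magnitudes[ok]; mots <- mots[ok]
  if (length(mots) < 3) stop("need at least 3 paired observations")
  if (stats::sd(mots) == 0) stop("constant MOTs: trend undefined")
  fit <- stats::lm(magnitudes ~ mots)
  co <- stats::coef(fit)
  # exact fits are legitimate inputs; silence the perfect-fit warning
  ci <- tryCatch(suppressWarnings(stats::confint(fit)["mots", ]),
                 error = function(e) c(NA, NA))
  if (stats::sd(magnitudes) == 0) {
    rho <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::cor.test(mots, magnitudes,
                                           method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 rho = rho, p = p, n = length(mots),
                 slope_ci95 = unname(ci)),
            class = "trend_result")
}

#' Magnitudes binned by MOT
#'
#' Mean, SEM and count of per-trial magnitudes within consecutive
#' half-open MOT bins tiling from 0 (default 500 ms wide); empty bins are
#' omitted. A MOT exactly on a boundary belongs to the upper bin.
#'
#' @param magnitudes Per-trial percent magnitudes.
#' @param mots Per-trial MOTs (s).
#' @param bin_width_s Bin width in seconds.
#' @return data.frame: bin_start_s, bin_end_s, mean, sem, n.
#' @export
mot_binned_magnitudes <- function(magnitudes, mots, bin_width_s = 0.5) {
  if (bin_width_s <= 0) stop("bin width must be > 0")
  ok <- !is.na(magnitudes) & !is.na(mots)
  magnitudes <- magnitudes[ok]; mots <- mots[ok]
  bin <- floor(mots / bin_width_s)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    m <- magnitudes[bin == b]
    data.frame(bin_start_s = b * bin_width_s,
               bin_end_s = (b + 1) * bin_width_s,
               mean = mean(m),
               sem = if (length(m) > 1) stats::sd(m) / sqrt(length(m)) else NA_real_,
               n = length(m))
  }))
  rownames(out) <- NULL
  out
}

#' Find runs of consecutive correct trials
#'
#' Maximal chronological runs of correct trials of length at least
#' `min_len`, with short and long intervals pooled to preserve the trial
#' order. Indices refer to `trial_index`.
#'
#' @param trials Trial-event data.frame with classified outcomes, or a
#'   `tan_session`.
#' @param min_len Minimum run length.
#' @return data.frame: start_index, end_index, length.
#' @export
find_correct_runs <- function(trials, min_len = 5) {
  if (inherits(trials, "tan_session")) trials <- trials$trials
  outc <- trials$outcome
  flags <- !is.na(outc) & outc == "correct"
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_len)
  out <- data.frame(start_index = trials$trial_index[starts[hit]],
                    end_index = trials$trial_index[ends[hit]],
                    length = r$lengths[hit])
  rownames(out) <- NULL
  out
}

#' Trend of response magnitude across a correct-trial sequence
#'
#' Within runs of consecutive correct trials, per-trial magnitudes are
#' averaged across units at each 1-based within-run position (pooled over
#' runs), and a linear plus Spearman trend of that average against the
#' position is computed. A deepening cue pause across the run gives a
#' negative slope (magnitude grows more negative); a weakening reward
#' pause gives a positive one.
#'
#' @param trial_mags data.frame from [trial_magnitudes()] (columns
#'   unit_id, trial_index, magnitude).
#' @param runs data.frame from [find_correct_runs()].
#' @return List of class `trend_result` (see [mot_trend()]) with an extra
#'   `positions` data.frame (position, mean_magnitude, n_trials); `NULL`
#'   when there are no runs.
#' @export
sequence_trend <- function(trial_mags, runs) {
  if (is.null(runs) || nrow(runs) == 0) return(NULL)
  rows <- list()
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start_index[k]:runs$end_index[k]
    for (p in seq_along(idx)) {
      m <- trial_mags$magnitude[trial_mags$trial_index == idx[p]]
      if (length(m)) {
        rows[[length(rows) + 1L]] <- data.frame(run = k, position = p,
                                                magnitude = mean(m))
      }
    }
  }
  pts <- do.call(rbind, rows)
  if (is.null(pts) || length(unique(pts$position)) < 2) {
    stop("need at least 2 distinct within-run positions")
  }
  tr <- mot_trend(pts$magnitude, pts$position)
  agg <- stats::aggregate(magnitude ~ position, pts, mean)
  n_at <- as.vector(table(pts$position))
  tr$positions <- data.frame(position = agg$position,
                             mean_magnitude = agg$magnitude,
                             n_trials = n_at)
  tr
}

#' Regional contrast of cue responsiveness
#'
#' Compares TAN cue responses between motor and associative striatum: a
#' chi-square test on the response frequencies and, per interval, an
#' unpaired rank test on the magnitudes.
#'
#' @param mag_table A [magnitude_table()] joined with unit regions, i.e.
#'   containing columns `unit_id, interval, magnitude, region`.
#' @param responsive data.frame with columns `unit_id, region,
#'   responsive` (logical; e.g. detected cue pause on either interval).
#' @return List: `frequency` (a `contingency_result`), `magnitude` (named
#'   list of `rank_test_result` per interval).
#' @export
region_contrast <- function(mag_table, responsive) {
  regs <- c("associative", "motor")
  if (!all(regs %in% responsive$region)) stop("both regions must be populated")
  x1 <- sum(responsive$responsive[responsive$region == "associative"])
  n1 <- sum(responsive$region == "associative")
  x2 <- sum(responsive$responsive[responsive$region == "motor"])
  n2 <- sum(responsive$region == "motor")
  freq <- prop_chi2(x1, n1, x2, n2)
  mags <- lapply(c(short = "short", long = "long"), function(iv) {
    a <- mag_table$magnitude[mag_table$interval == iv &
                               mag_table$region == "associative"]
    m <- mag_table$magnitude[mag_table$interval == iv &
                               mag_table$region == "motor"]
    rank_compare(a, m, paired = FALSE)
  })
  list(frequency = freq, magnitude = mags)
}
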