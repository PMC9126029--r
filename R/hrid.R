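## Haplotype Richness Drop (HRiD): effective number of haplotypes in
## SNP-count windows over hemizygous male haplotypes, the drop score with
## edge-window variants, its normalization, and signal merging.

#' Build SNP-count windows over the hemizygous region
#'
#' Window i covers SNP indices `[1 + step*(i-1), size + step*(i-1)]`; only
#' full windows of exactly `size` SNPs are emitted, so a trailing remainder
#' shorter than `size` is left unscanned (effective-number-of-haplotype
#' values are only comparable between windows holding the same number of
#' SNPs).
#'
#' @param snpmap_nonpar SNP map restricted to non-PAR SNPs (needs `pos_bp`),
#'   or a bare vector of positions.
#' @param size window size in SNPs (default 70).
#' @param step slide in SNPs (default 35; half-overlapping windows).
#' @return data.frame with `index`, `first_snp_idx`, `last_snp_idx`,
#'   `start_bp`, `end_bp`.
#' @export
build_windows <- function(snpmap_nonpar, size = 70, step = 35) {
  pos <- if (is.data.frame(snpmap_nonpar)) snpmap_nonpar$pos_bp else
    as.integer(snpmap_nonpar)
  stopifnot(size > 0, step > 0, step <= size)
  n <- length(pos)
  if (n < size) stop("fewer SNPs (", n, ") than the window size (", size, ")")
  starts <- seq(1L, n - size + 1L, by = step)
  data.frame(index = seq_along(starts),
             first_snp_idx = starts,
             last_snp_idx = starts + size - 1L,
             start_bp = pos[starts],
             end_bp = pos[starts + size - 1L])
}

#' Haplotype counts within one window
#'
#' Males whose haplotype has a fraction of missing calls above
#' `max_missing_frac` inside the window are excluded; the remaining
#' haplotype strings are collapsed into unique haplotypes with counts.
#'
#' @param male_haps a [phased_haplotypes()] of hemizygous males (or a 0/1
#'   matrix, haplotypes x SNPs).
#' @param window one row of [build_windows()] output (or a list with
#'   `first_snp_idx`, `last_snp_idx`).
#' @param max_missing_frac maximum tolerated fraction of missing calls per
#'   male within the window (default 0: any missing call excludes).
#' @return list with `counts` (named integer vector per unique haplotype),
#'   `n_males_used`, `n_a` (number of unique haplotypes) and `usable`
#'   (`FALSE` when every male was excluded).
#' @export
window_haplotype_counts <- function(male_haps, window, max_missing_frac = 0) {
  H <- if (inherits(male_haps, "phased_haplotypes")) male_haps$haps else
    as.matrix(male_haps)
  cols <- seq(window$first_snp_idx, window$last_snp_idx)
  sub <- H[, cols, drop = FALSE]
  miss_frac <- rowMeans(is.na(sub))
  keep <- miss_frac <= max_missing_frac
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(list(counts = integer(0), n_males_used = 0L, n_a = 0L,
                usable = FALSE))
  }
  key <- apply(sub, 1, paste, collapse = "")
  counts <- table(key)
  list(counts = setNames(as.integer(counts), names(counts)),
       n_males_used = nrow(sub), n_a = length(counts), usable = TRUE)
}

#' Effective number of haplotypes
#'
#' The reciprocal of the sum of squared haplotype frequencies,
#' n_h = 1 / sum(p_k^2) — the haplotype analogue of the effective number of
#' alleles. Equals the number of distinct haplotypes when they are
#' equifrequent and 1 when a single haplotype is present.
#'
#' @param counts integer vector of haplotype counts (total >= 1).
#' @return Numeric n_h in `[1, length(counts)]`.
#' @export
effective_num_haplotypes <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty haplotype counts")
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Haplotype Richness Drop scores over a window series
#'
#' For interior windows, HRiD_i = (n_h(w_{i-1}) + n_h(w_{i+1})) / (2 n_h(w_i)):
#' the mean richness of the two flanking windows relative to the focal one.
#' The edge windows use the single available neighbour in the numerator
#' (first: 2 n_h(w_2) / (2 n_h(w_1)); last: 2 n_h(w_{L-1}) / (2 n_h(w_L))), so
#' selection signals at the chromosome ends remain detectable. Without
#' selection HRiD fluctuates around 1; a sudden drop in richness inflates it.
#' An unusable (`NA`) neighbour propagates `NA` — the other neighbour is never
#' silently substituted.
#'
#' @param windows data.frame with a numeric `n_h` column (NA for unusable
#'   windows), ordered by window index.
#' @return `windows` with an `hrid` column added.
#' @export
hrid_scores <- function(windows) {
  nh <- windows$n_h
  L <- length(nh)
  if (L < 2) stop("need at least two windows to score HRiD")
  hrid <- rep(NA_real_, L)
  if (L >= 3) {
    i <- 2:(L - 1)
    hrid[i] <- (nh[i - 1] + nh[i + 1]) / (2 * nh[i])
  }
  hrid[1] <- (2 * nh[2]) / (2 * nh[1])
  hrid[L] <- (2 * nh[L - 1]) / (2 * nh[L])
  windows$hrid <- hrid
  windows
}

#' Normalize HRiD and flag significant windows
#'
#' HRiD values are z-standardized over the non-`NA` windows and converted to
#' -log10 of the one-sided upper-tail standard-normal probability; only
#' richness drops (high HRiD) are evidence of positive selection. Windows at
#' or above `threshold` are flagged significant.
#'
#' @param windows data.frame with an `hrid` column (from [hrid_scores()]).
#' @param threshold significance level on -log10 p (default 3.3).
#' @return `windows` with `neglogp` and `significant` columns.
#' @export
hrid_neglogp <- function(windows, threshold = 3.3) {
  h <- windows$hrid
  ok <- !is.na(h)
  if (sum(ok) < 2) stop("need at least two scored windows")
  s <- sd(h[ok])
  if (s == 0) stop("zero variance in HRiD values; normalization undefined")
  z <- (h - mean(h[ok])) / s
  windows$neglogp <- ifelse(ok, neglog10_upper(z), NA_real_)
  windows$significant <- !is.na(windows$neglogp) & windows$neglogp >= threshold
  windows
}

#' Merge significant HRiD windows into signals
#'
#' With `merge = TRUE`, overlapping or adjacent (in window index) significant
#' windows are unioned into one signal spanning their combined bp range; with
#' `merge = FALSE` each significant window is reported as its own signal
#' (per-window reporting mode). Both modes report the peak HRiD and peak
#' -log10 p among member windows.
#'
#' @param windows output of [hrid_neglogp()].
#' @param merge union consecutive significant windows (default `TRUE`).
#' @return data.frame with `start_bp`, `end_bp`, `n_windows`,
#'   `member_indices`, `peak_hrid`, `peak_neglogp`.
#' @export
hrid_signals <- function(windows, merge = TRUE) {
  sig <- windows[windows$significant %in% TRUE, , drop = FALSE]
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_windows = integer(), member_indices = character(),
                      peak_hrid = numeric(), peak_neglogp = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  if (!merge) {
    groups <- as.list(seq_len(nrow(sig)))
  } else {
    brk <- c(0, which(diff(sig$index) > 1), nrow(sig))
    groups <- lapply(seq_len(length(brk) - 1),
                     function(g) (brk[g] + 1):brk[g + 1])
  }
  out <- lapply(groups, function(g) {
    s <- sig[g, , drop = FALSE]
    data.frame(start_bp = min(s$start_bp), end_bp = max(s$end_bp),
               n_windows = nrow(s),
               member_indices = paste(s$index, collapse = ","),
               peak_hrid = max(s$hrid), peak_neglogp = max(s$neglogp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full HRiD scan over hemizygous male haplotypes
#'
#' Convenience wrapper: windows are built over the haplotype positions,
#' haplotype counts and effective numbers computed per window, HRiD scored,
#' normalized, and significant windows merged into signals.
#'
#' @param male_haps a [phased_haplotypes()] of hemizygous males (non-PAR), as
#'   from [hemizygous_haplotypes()].
#' @param size,step window size and slide in SNPs (defaults 70 / 35).
#' @param threshold significance level on -log10 p (default 3.3).
#' @param max_missing_frac per-window missing-call tolerance per male.
#' @param merge_signals union overlapping significant windows.
#' @return list with `windows` (per-window table: index, spans, n_males_used,
#'   n_a, n_h, hrid, neglogp, significant) and `signals`.
#' @export
hrid_scan <- function(male_haps, size = 70, step = 35, threshold = 3.3,
                      max_missing_frac = 0, merge_signals = TRUE) {
  win <- build_windows(male_haps$pos_bp, size = size, step = step)
  stats <- lapply(seq_len(nrow(win)), function(i) {
    wc <- window_haplotype_counts(male_haps, win[i, ], max_missing_frac)
    data.frame(n_males_used = wc$n_males_used, n_a = wc$n_a,
               n_h = if (wc$usable) effective_num_haplotypes(wc$counts) else NA_real_)
  })
  win <- cbind(win, do.call(rbind, stats))
  win <- hrid_neglogp(hrid_scores(win), threshold = threshold)
  list(windows = win, signals = hrid_signals(win, merge = merge_signals))
}
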