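## Extreme ROH islands: class-specific ROH calling in diploid females,
## per-SNP ROH frequency, normal-tail -log10(P) transform, the simpleM
## effective number of tests, and consecutive-outlier signal calling.

#' ROH calling parameters
#'
#' Defaults follow array-density practice for a ~7 kb-spaced X map: runs of
#' at least 15 SNPs, adjacent-SNP gaps at most 250 kb, at least one SNP per
#' 20 kb, minimum length 0.25 Mb. Six length classes (0.25-1, 1-2, 2-4, 4-8,
#' 8-16, >16 Mb) carry their own heterozygote/missing allowances to absorb
#' the array's genotyping error over long runs; the 0.25-1 Mb class allows
#' neither. Allowances above 1 Mb are configurable assumptions.
#'
#' @param min_snps minimum SNPs per run.
#' @param max_gap_bp maximum gap between adjacent SNPs inside a run.
#' @param min_density_bp_per_snp maximum average spacing (bp per SNP).
#' @param min_len_bp minimum run length (end - start).
#' @param classes data.frame with `lo_bp`, `hi_bp`, `max_het`, `max_missing`;
#'   contiguous, non-overlapping length classes.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 15, max_gap_bp = 250000,
                       min_density_bp_per_snp = 20000, min_len_bp = 250000,
                       classes = NULL) {
  if (is.null(classes)) {
    classes <- data.frame(
      lo_bp = c(0.25, 1, 2, 4, 8, 16) * 1e6,
      hi_bp = c(1, 2, 4, 8, 16, Inf) * 1e6,
      max_het = c(0, 0, 0, 1, 2, 4),
      max_missing = c(0, 1, 2, 4, 8, 16))
  }
  if (any(classes$hi_bp[-nrow(classes)] != classes$lo_bp[-1])) {
    stop("length classes must be contiguous")
  }
  structure(list(min_snps = min_snps, max_gap_bp = max_gap_bp,
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 min_len_bp = min_len_bp, classes = classes),
            class = "roh_params")
}

## Maximal admissible runs for one genotype vector under one allowance set.
## A run is admissible when all internal gaps are <= max_gap and it contains
## at most max_het heterozygous and max_missing missing calls; maximal when
## no admissible extension exists. Two-pointer within big-gap chunks.
maximal_runs <- function(g, pos, max_gap, max_het, max_missing) {
  n <- length(g)
  if (n == 0) return(NULL)
  chunk <- cumsum(c(0, diff(pos) > max_gap))
  out <- list()
  for (ch in unique(chunk)) {
    idx <- which(chunk == ch)
    het <- as.integer(!is.na(g[idx]) & g[idx] == 1L)
    mis <- as.integer(is.na(g[idx]))
    m <- length(idx)
    e <- integer(m)
    j <- 0; nh <- 0; nm <- 0
    for (i in seq_len(m)) {
      if (j < i - 1) { j <- i - 1; nh <- 0; nm <- 0 }
      while (j < m && nh + het[j + 1] <= max_het && nm + mis[j + 1] <= max_missing) {
        j <- j + 1; nh <- nh + het[j]; nm <- nm + mis[j]
      }
      e[i] <- j
      nh <- nh - het[i]; nm <- nm - mis[i]
    }
    starts <- which(c(TRUE, e[-m] < e[-1]) & e >= seq_len(m))
    for (s in starts) {
      out[[length(out) + 1]] <- c(idx[s], idx[e[s]])
    }
  }
  do.call(rbind, out)
}

#' Call runs of homozygosity in diploid females
#'
#' Scans each female separately for each length class: a run must hold at
#' least `min_snps` SNPs, have no adjacent-SNP gap above `max_gap_bp`, meet
#' the density constraint, span at least `min_len_bp`, respect its class's
#' heterozygote/missing allowance, and be maximal (not extendable without
#' violating the allowance). Per-class scans are independent; a run is
#' reported under the class containing its bp length.
#'
#' @param gm_females a [genotype_matrix()] holding diploid females only.
#' @param params a [roh_params()] object.
#' @return data.frame of segments: `sample_id`, `start_bp`, `end_bp`,
#'   `n_snps`, `n_het`, `n_missing`, `length_bp`, `length_class`.
#' @export
call_roh <- function(gm_females, params = roh_params()) {
  if (any(gm_females$samples$sex != "female")) {
    stop("call_roh expects diploid females only; subset the genotype matrix")
  }
  pos <- gm_females$map$pos_bp
  cls <- params$classes
  segs <- list()
  for (s in seq_len(ncol(gm_females$calls))) {
    g <- gm_females$calls[, s]
    for (ci in seq_len(nrow(cls))) {
      runs <- maximal_runs(g, pos, params$max_gap_bp,
                           cls$max_het[ci], cls$max_missing[ci])
      if (is.null(runs)) next
      for (r in seq_len(nrow(runs))) {
        i <- runs[r, 1]; j <- runs[r, 2]
        n_snp <- j - i + 1
        len <- pos[j] - pos[i]
        if (n_snp < params$min_snps) next
        if (len < params$min_len_bp) next
        if (len / n_snp > params$min_density_bp_per_snp) next
        if (len < cls$lo_bp[ci] || len >= cls$hi_bp[ci]) next
        gi <- g[i:j]
        segs[[length(segs) + 1]] <- data.frame(
          sample_id = gm_females$samples$sample_id[s],
          start_bp = pos[i], end_bp = pos[j], n_snps = n_snp,
          n_het = sum(gi == 1L, na.rm = TRUE), n_missing = sum(is.na(gi)),
          length_bp = len,
          length_class = paste0(cls$lo_bp[ci] / 1e6, "-",
                                ifelse(is.finite(cls$hi_bp[ci]),
                                       cls$hi_bp[ci] / 1e6, "Inf"), "Mb"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(segs) == 0) {
    return(data.frame(sample_id = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      n_het = integer(), n_missing = integer(),
                      length_bp = integer(), length_class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, segs)
}

#' Per-SNP ROH frequency
#'
#' For each SNP, the fraction of females carrying at least one ROH covering
#' it (a female is counted once per SNP regardless of how many of her runs
#' overlap it, across all length classes).
#'
#' @param segments data.frame from [call_roh()] (union over classes).
#' @param snpmap SNP map with `pos_bp`.
#' @param n_females number of females scanned.
#' @return data.frame with `snp_id`, `pos_bp`, `count`, `frequency`.
#' @export
snp_roh_frequency <- function(segments, snpmap, n_females) {
  pos <- snpmap$pos_bp
  count <- integer(length(pos))
  for (id in unique(segments$sample_id)) {
    s <- segments[segments$sample_id == id, , drop = FALSE]
    cov <- logical(length(pos))
    for (r in seq_len(nrow(s))) {
      cov <- cov | (pos >= s$start_bp[r] & pos <= s$end_bp[r])
    }
    count <- count + cov
  }
  data.frame(snp_id = snpmap$snp_id, pos_bp = pos, count = count,
             frequency = count / n_females, stringsAsFactors = FALSE)
}

#' Normal-tail -log10(P) transform of ROH frequencies
#'
#' Frequencies are z-standardized over SNPs and converted to the -log10 of
#' the one-sided upper-tail standard-normal probability: only unusually
#' frequent ROH coverage (autozygosity hotspots) counts as evidence.
#'
#' @param freqs data.frame from [snp_roh_frequency()].
#' @return `freqs` with `z` and `neglogp` columns added.
#' @export
roh_neglogp <- function(freqs) {
  f <- freqs$frequency
  s <- sd(f)
  if (is.na(s) || s == 0) stop("zero variance in ROH frequencies")
  freqs$z <- (f - mean(f)) / s
  freqs$neglogp <- neglog10_upper(freqs$z)
  freqs
}

#' simpleM effective number of independent tests
#'
#' Eigen-decomposes the SNP-SNP composite-LD correlation matrix (Pearson
#' correlation of genotype dosages) and reports the smallest number of
#' principal components whose cumulative eigenvalue share reaches
#' `variance_explained`, plus the Bonferroni-style threshold
#' -log10(0.05 / m_eff). Constant SNPs are excluded before decomposition.
#'
#' @param gm a [genotype_matrix()] or a SNP x sample dosage matrix.
#' @param variance_explained cumulative eigenvalue share (default 0.995).
#' @param alpha family-wise error rate for the threshold (default 0.05).
#' @return list with `m_snps`, `m_eff`, `threshold_neglogp`.
#' @export
simple_m <- function(gm, variance_explained = 0.995, alpha = 0.05) {
  calls <- if (inherits(gm, "genotype_matrix")) gm$calls else as.matrix(gm)
  if (nrow(calls) < 1 || ncol(calls) < 2) stop("need >= 1 SNP and >= 2 samples")
  x <- t(calls)  # samples x SNPs
  keep <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) >= 2 && var(v) > 0
  })
  x <- x[, keep, drop = FALSE]
  m <- ncol(x)
  if (m == 0) stop("no variable SNPs")
  if (m == 1) {
    return(list(m_snps = 1L, m_eff = 1L,
                threshold_neglogp = -log10(alpha)))
  }
  cc <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  m_eff <- which(cumsum(ev) / sum(ev) >= variance_explained)[1]
  list(m_snps = m, m_eff = as.integer(m_eff),
       threshold_neglogp = -log10(alpha / m_eff))
}

#' Call eROHi signals from consecutive outlier SNPs
#'
#' Maximal runs of at least `min_consecutive` consecutive outlier SNPs
#' (neglogp at or above `threshold`, adjacency in map order) become signals,
#' ranked by the highest -log10 p within each signal (the signal peak).
#'
#' @param snp_freqs data.frame from [roh_neglogp()].
#' @param threshold outlier level on -log10 p (default 3.3, `>=`).
#' @param min_consecutive minimum consecutive outlier SNPs per signal.
#' @return data.frame with `start_bp`, `end_bp`, `n_outlier_snps`,
#'   `peak_neglogp`, ordered by descending peak.
#' @export
call_erohi_signals <- function(snp_freqs, threshold = 3.3, min_consecutive = 2) {
  out <- snp_freqs$neglogp >= threshold
  out[is.na(out)] <- FALSE
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_outlier_snps = integer(), peak_neglogp = numeric())
  if (!any(out)) return(empty)
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_consecutive
  if (!any(keep)) return(empty)
  sig <- do.call(rbind, lapply(which(keep), function(k) {
    i <- starts[k]; j <- ends[k]
    data.frame(start_bp = snp_freqs$pos_bp[i], end_bp = snp_freqs$pos_bp[j],
               n_outlier_snps = j - i + 1,
               peak_neglogp = max(snp_freqs$neglogp[i:j]))
  }))
  sig[order(-sig$peak_neglogp), , drop = FALSE]
}
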