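## Phased-haplotype container plus the EHH / iHS / nSL scan stack:
## per-SNP raw scores, frequency-bin standardization, and sliding-window
## outlier aggregation.

#' Construct a phased-haplotype set
#'
#' Haplotypes in rows, SNPs in columns, states 0/1 (`NA` allowed for missing
#' calls). Outside the PAR, males contribute exactly one haplotype (their
#' hemizygous X is the haplotype); females contribute two.
#'
#' @param haps integer matrix, haplotypes x SNPs, values 0/1/`NA`.
#' @param pos_bp SNP positions (1-based, strictly increasing).
#' @param meta data.frame with one row per haplotype: `sample_id`, `copy`
#'   (1 or 2), `sex`, `population`, `species`.
#' @param snp_id optional SNP identifiers.
#' @param coding `"allele_b"` (0 = allele a) or `"ancestral"`
#'   (0 = ancestral, 1 = derived).
#' @return An object of class `phased_haplotypes`.
#' @export
phased_haplotypes <- function(haps, pos_bp, meta, snp_id = NULL,
                              coding = c("allele_b", "ancestral")) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (any(!is.na(haps) & !(haps %in% 0:1))) stop("haplotype states must be 0/1/NA")
  if (length(pos_bp) != ncol(haps)) stop("pos_bp length != number of SNPs")
  if (is.unsorted(pos_bp, strictly = TRUE)) stop("pos_bp must be strictly increasing")
  if (nrow(meta) != nrow(haps)) stop("meta rows != number of haplotypes")
  structure(list(haps = haps, pos_bp = as.integer(pos_bp),
                 snp_id = snp_id %||% paste0("snp", seq_along(pos_bp)),
                 meta = as.data.frame(meta, stringsAsFactors = FALSE),
                 coding = match.arg(coding)),
            class = "phased_haplotypes")
}

#' @exportS3Method base::print
print.phased_haplotypes <- function(x, ...) {
  cat("phased_haplotypes:", nrow(x$haps), "haplotypes x", ncol(x$haps),
      "SNPs (", x$coding, "coding )\n")
  invisible(x)
}

#' Extract hemizygous male haplotypes from genotypes
#'
#' Outside the PAR a male genotype is his haplotype: dosage 0 maps to state 0,
#' dosage 2 to state 1, missing to `NA`. Only non-PAR SNPs are used. Calls of
#' dosage 1 (should not exist after [clean_hemizygous()]) are set `NA` with a
#' warning.
#'
#' @param gm a [genotype_matrix()] with `in_par` flagged.
#' @param species restrict to `"focal"`, `"outgroup"`, or `"both"`.
#' @return A [phased_haplotypes()] in allele-b coding, one row per male.
#' @export
hemizygous_haplotypes <- function(gm, species = c("focal", "outgroup", "both")) {
  species <- match.arg(species)
  keep <- gm$samples$sex == "male"
  if (species != "both") keep <- keep & gm$samples$species == species
  if (!any(keep)) stop("no males of requested species")
  hemi <- !gm$map$in_par
  if (!any(hemi)) stop("no non-PAR SNPs in map")
  d <- gm$calls[hemi, keep, drop = FALSE]
  if (any(d == 1L, na.rm = TRUE)) {
    warning("male heterozygous calls outside the PAR set to NA; run clean_hemizygous first")
    d[d == 1L] <- NA_integer_
  }
  h <- t(d / 2L)
  s <- gm$samples[keep, , drop = FALSE]
  phased_haplotypes(h, gm$map$pos_bp[hemi],
                    data.frame(sample_id = s$sample_id, copy = 1L, sex = s$sex,
                               population = s$population, species = s$species,
                               stringsAsFactors = FALSE),
                    snp_id = gm$map$snp_id[hemi], coding = "allele_b")
}

#' Read phased haplotypes from a VCF
#'
#' Diploid samples must be phased (`|` separator) at heterozygous sites and
#' contribute two haplotypes; samples with haploid GT fields (hemizygous
#' males) contribute one. Mixed-ploidy samples take their first allele.
#' Unphased heterozygous diploid calls are an error: the package does no
#' statistical phasing.
#'
#' @param path VCF file with GT fields.
#' @param sample_sheet sample metadata (data.frame or path).
#' @return A [phased_haplotypes()] in allele-b coding.
#' @export
read_phased_vcf <- function(path, sample_sheet) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  sample_sheet <- as_sample_info(sample_sheet)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !(grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == ".")
  if (!all(keep)) warning(sum(!keep), " non-biallelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- colnames(gt)
  idx <- match(ids, sample_sheet$sample_id)
  if (anyNA(idx)) stop("sample ids absent from sample sheet")
  unphased_het <- grepl("/", gt) & substr(gt, 1, 1) != substr(gt, 3, 3) &
    !grepl("\\.", gt)
  if (any(unphased_het)) {
    stop("unphased heterozygous diploid calls found; provide phased input")
  }
  hap_rows <- list()
  meta_rows <- list()
  parse_allele <- function(ch) ifelse(ch == "1", 1L, ifelse(ch == "0", 0L, NA_integer_))
  for (j in seq_along(ids)) {
    g <- gt[, j]
    diploid <- any(nchar(g) > 1, na.rm = TRUE)
    s <- sample_sheet[idx[j], ]
    h1 <- parse_allele(substr(g, 1, 1))
    hap_rows[[length(hap_rows) + 1]] <- h1
    meta_rows[[length(meta_rows) + 1]] <-
      data.frame(sample_id = s$sample_id, copy = 1L, sex = s$sex,
                 population = s$population, species = s$species,
                 stringsAsFactors = FALSE)
    if (diploid) {
      h2 <- parse_allele(substr(g, 3, 3))
      hap_rows[[length(hap_rows) + 1]] <- h2
      meta_rows[[length(meta_rows) + 1]] <-
        data.frame(sample_id = s$sample_id, copy = 2L, sex = s$sex,
                   population = s$population, species = s$species,
                   stringsAsFactors = FALSE)
    }
  }
  phased_haplotypes(do.call(rbind, hap_rows), as.integer(fix$POS),
                    do.call(rbind, meta_rows), snp_id = fix$ID,
                    coding = "allele_b")
}

## Pair-identity fractions outward from a core SNP for one carrier set.
## Returns, for each step s = 0, 1, ..., the fraction of carrier pairs whose
## haplotypes are identical from the core through the s-th SNP in the given
## direction (step 0 is the core itself, fraction 1 by construction).
## Stops once the fraction reaches stop_below (and records that point) or the
## chromosome ends. NA states never match, so missing data break identity.
pair_identity_walk <- function(haps, carriers, core, direction, stop_below = 0) {
  n_c <- length(carriers)
  npairs <- choose(n_c, 2)
  step_idx <- if (direction == "right") {
    seq(core, ncol(haps))
  } else {
    seq(core, 1)
  }
  grp <- rep(1L, n_c)
  out <- numeric(length(step_idx))
  for (k in seq_along(step_idx)) {
    col <- haps[carriers, step_idx[k]]
    key <- paste(grp, ifelse(is.na(col), paste0("na", seq_len(n_c)), col))
    grp <- match(key, unique(key))
    tab <- tabulate(grp)
    out[k] <- sum(choose(tab, 2)) / npairs
    if (out[k] < stop_below || out[k] == 0) {
      out <- out[seq_len(k)]
      step_idx <- step_idx[seq_len(k)]
      break
    }
  }
  list(frac = out, snp_idx = step_idx)
}

#' Extended haplotype homozygosity decay from a core SNP
#'
#' EHH at distance 0 is 1; at each successive SNP it is the probability that
#' two randomly drawn carriers of `allele` at the core are identical over all
#' SNPs from the core to that point, computed as
#' sum over identity groups g of C(n_g, 2) / C(n_carriers, 2). The curve is
#' truncated at the first point falling below `cutoff` (that point is
#' retained) or at the chromosome end.
#'
#' @param haps a [phased_haplotypes()] or 0/1 matrix.
#' @param core_snp core SNP column index.
#' @param allele core allele (0 or 1) defining the carrier set.
#' @param direction `"left"` or `"right"` from the core.
#' @param cutoff truncation level for the decay curve.
#' @return data.frame with `pos_bp`, `snp_idx`, `ehh`, or `NULL` when fewer
#'   than two carriers exist.
#' @export
ehh <- function(haps, core_snp, allele, direction = c("right", "left"),
                cutoff = 0.05) {
  direction <- match.arg(direction)
  H <- if (inherits(haps, "phased_haplotypes")) haps$haps else as.matrix(haps)
  pos <- if (inherits(haps, "phased_haplotypes")) haps$pos_bp else
    seq_len(ncol(H))
  carriers <- which(!is.na(H[, core_snp]) & H[, core_snp] == allele)
  if (length(carriers) < 2) return(NULL)
  w <- pair_identity_walk(H, carriers, core_snp, direction, stop_below = cutoff)
  data.frame(pos_bp = pos[w$snp_idx], snp_idx = w$snp_idx, ehh = w$frac)
}

#' Integrated EHH (trapezoidal integral over physical distance)
#'
#' Integrates an EHH decay curve over base pairs using the trapezoidal rule.
#' Given a list with `left` and `right` curves (as from [ehh()]), the two
#' sides are integrated separately and summed; an empty (`NULL`) side
#' contributes 0.
#'
#' @param curve data.frame from [ehh()] or `list(left =, right =)` of such.
#' @return Numeric iHH value.
#' @export
ihh <- function(curve) {
  if (is.null(curve)) return(0)
  if (is.data.frame(curve)) {
    if (nrow(curve) < 2) return(0)
    d <- abs(diff(curve$pos_bp))
    return(sum(d * (head(curve$ehh, -1) + tail(curve$ehh, -1)) / 2))
  }
  ihh(curve$left) + ihh(curve$right)
}

## Core scorer shared by ihs_raw and nsl_raw. mode "ihs": trapezoid integral
## of the pair-identity curve over bp, truncated at `cutoff`; mode "nsl":
## sum of pair-identity fractions over SNP steps (counting the core), no
## cutoff — this equals the mean pairwise tract length in SNPs.
allele_class_stat <- function(H, pos, core, allele, mode, cutoff) {
  carriers <- which(!is.na(H[, core]) & H[, core] == allele)
  if (length(carriers) < 2) return(NA_real_)
  stopb <- if (mode == "ihs") cutoff else 0
  val <- 0
  for (dir in c("left", "right")) {
    w <- pair_identity_walk(H, carriers, core, dir, stop_below = stopb)
    if (mode == "ihs") {
      if (length(w$frac) >= 2) {
        d <- abs(diff(pos[w$snp_idx]))
        val <- val + sum(d * (head(w$frac, -1) + tail(w$frac, -1)) / 2)
      }
    } else {
      val <- val + sum(w$frac[-1])   # steps beyond the core
    }
  }
  if (mode == "nsl") val <- val + 1  # the core SNP itself
  val
}

raw_scan <- function(haps, snpmap = NULL, maf_floor, mode, cutoff = 0.05) {
  stopifnot(inherits(haps, "phased_haplotypes"))
  if (haps$coding != "ancestral") {
    stop("haplotypes must be in ancestral coding; apply recode_ancestral first")
  }
  H <- haps$haps
  pos <- haps$pos_bp
  n_snp <- ncol(H)
  anc_known <- if (is.null(snpmap)) rep(TRUE, n_snp) else
    snpmap$ancestral != "unknown"
  freq <- colMeans(H == 1L, na.rm = TRUE)
  raw <- rep(NA_real_, n_snp)
  for (j in seq_len(n_snp)) {
    f <- freq[j]
    if (is.na(f) || !anc_known[j]) next
    if (min(f, 1 - f) < maf_floor) next
    s_anc <- allele_class_stat(H, pos, j, 0L, mode, cutoff)
    s_der <- allele_class_stat(H, pos, j, 1L, mode, cutoff)
    if (is.na(s_anc) || is.na(s_der) || s_anc == 0 || s_der == 0) next
    raw[j] <- log(s_anc / s_der)
  }
  data.frame(snp_id = haps$snp_id, pos_bp = pos, derived_freq = freq,
             raw = raw, stringsAsFactors = FALSE)
}

#' Raw (unstandardized) iHS per SNP
#'
#' For each core SNP, the log-ratio ln(iHH_ancestral / iHH_derived) of the
#' integrated EHH of the two allele classes. SNPs with minor allele frequency
#' below `maf_floor`, unknown ancestral state, fewer than two carriers of
#' either allele, or a zero integral get `NA`.
#'
#' @param haps a [phased_haplotypes()] in ancestral coding (see
#'   [recode_ancestral()]).
#' @param snpmap optional SNP map supplying `ancestral`; when `NULL` all SNPs
#'   are assumed resolved.
#' @param maf_floor minimum minor allele frequency (default 0.05).
#' @param cutoff EHH truncation level.
#' @return data.frame with `snp_id`, `pos_bp`, `derived_freq`, `raw`.
#' @export
ihs_raw <- function(haps, snpmap = NULL, maf_floor = 0.05, cutoff = 0.05) {
  raw_scan(haps, snpmap, maf_floor, mode = "ihs", cutoff = cutoff)
}

#' Raw (unstandardized) nSL per SNP
#'
#' As iHS, but haplotype length is measured in number of SNPs rather than
#' physical distance: for each allele class the statistic is the mean, over
#' carrier pairs, of the number of consecutive SNPs (counting the core) over
#' which the pair is identical, extended in both directions without a decay
#' cutoff. Raw score is ln(SL_ancestral / SL_derived); `NA` rules as for
#' [ihs_raw()].
#'
#' @inheritParams ihs_raw
#' @return data.frame with `snp_id`, `pos_bp`, `derived_freq`, `raw`.
#' @export
nsl_raw <- function(haps, snpmap = NULL, maf_floor = 0.05) {
  raw_scan(haps, snpmap, maf_floor, mode = "nsl")
}

#' Standardize scan scores within derived-allele-frequency bins
#'
#' Raw scores are z-standardized within bins of derived allele frequency of
#' width `bin_width`; bins holding fewer than `min_bin_count` non-`NA` scores
#' are merged with their nearest neighbouring bin before standardization
#' (preventing zero-variance artifacts). The two-sided normal
#' -log10 p is attached, treating both extreme tails as informative.
#'
#' @param scores data.frame from [ihs_raw()] or [nsl_raw()].
#' @param bin_width derived-frequency bin width (default 0.025).
#' @param min_bin_count minimum non-`NA` scores per bin before merging.
#' @return `scores` with columns `z` and `neglogp` added.
#' @export
bin_standardize <- function(scores, bin_width = 0.025, min_bin_count = 10) {
  out <- scores
  out$z <- NA_real_
  out$neglogp <- NA_real_
  ok <- !is.na(scores$raw)
  if (!any(ok)) return(out)
  bin <- pmin(floor(scores$derived_freq / bin_width),
              ceiling(1 / bin_width) - 1)
  ## merge sparse bins into the nearest occupied neighbour
  repeat {
    tab <- table(bin[ok])
    small <- names(tab)[tab < min_bin_count]
    if (length(small) == 0 || length(tab) == 1) break
    b <- as.integer(small[1])
    others <- as.integer(setdiff(names(tab), small[1]))
    if (length(others) == 0) {
      others <- as.integer(setdiff(names(table(bin[ok])), small[1]))
      if (length(others) == 0) break
    }
    nearest <- others[which.min(abs(others - b))]
    bin[bin == b] <- nearest
  }
  for (b in unique(bin[ok])) {
    sel <- ok & bin == b
    v <- scores$raw[sel]
    mu <- mean(v)
    s <- sd(v)
    z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mu) / s
    out$z[sel] <- z
    out$neglogp[sel] <- neglog10_twosided(z)
  }
  out
}

#' Sliding-window outlier scan over standardized scores
#'
#' Windows of `win_bp` tiled every `slide_bp` along the chromosome; within
#' each, the proportion of scored (non-`NA`) SNPs whose -log10 p exceeds
#' `outlier_neglogp` is computed. Candidate windows with proportion above
#' `prop_threshold` are selected greedily by descending proportion with
#' overlap suppression, so the reported significant windows are
#' non-overlapping and ordered by their proportion.
#'
#' @param scores standardized scores from [bin_standardize()].
#' @param win_bp window size in bp (default 500 kb).
#' @param slide_bp slide in bp (default 100 kb).
#' @param outlier_neglogp per-SNP outlier level (default 2, strict `>`).
#' @param prop_threshold window significance proportion (default 0.10,
#'   strict `>`).
#' @return data.frame of significant windows (`start_bp`, `end_bp`, `n_snps`,
#'   `n_scored`, `n_outliers`, `proportion`), ordered by proportion; all
#'   evaluated windows in attribute `"all_windows"`.
#' @export
window_outlier_scan <- function(scores, win_bp = 500000, slide_bp = 100000,
                                outlier_neglogp = 2.0, prop_threshold = 0.10) {
  pos <- scores$pos_bp
  starts <- seq(slide_bp * floor(min(pos) / slide_bp), max(pos), by = slide_bp)
  rows <- lapply(starts, function(s) {
    e <- s + win_bp - 1
    inw <- pos >= s & pos <= e
    if (!any(inw)) return(NULL)
    scored <- inw & !is.na(scores$neglogp)
    if (!any(scored)) return(NULL)
    n_out <- sum(scores$neglogp[scored] > outlier_neglogp)
    data.frame(start_bp = s, end_bp = e, n_snps = sum(inw),
               n_scored = sum(scored), n_outliers = n_out,
               proportion = n_out / sum(scored))
  })
  wins <- do.call(rbind, rows)
  if (is.null(wins)) wins <- data.frame(start_bp = numeric(), end_bp = numeric(),
                                        n_snps = integer(), n_scored = integer(),
                                        n_outliers = integer(), proportion = numeric())
  cand <- wins[wins$proportion > prop_threshold, , drop = FALSE]
  cand <- cand[order(-cand$proportion, cand$start_bp), , drop = FALSE]
  sel <- cand[0, ]
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    sel <- rbind(sel, top)
    cand <- cand[cand$end_bp < top$start_bp | cand$start_bp > top$end_bp, ,
                 drop = FALSE]
  }
  rownames(sel) <- NULL
  attr(sel, "all_windows") <- wins
  sel
}
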