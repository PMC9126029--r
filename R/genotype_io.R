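## Genotype containers and I/O: PLINK bed/bim/fam and VCF readers, sample
## sheets, sex-aware QC, PAR localization from male heterozygosity, and
## ancestral-allele assignment from an outgroup.

#' Construct a genotype matrix object
#'
#' The central container of the package: an ordered SNP map, a sample table
#' with sex/population/species, and a SNP x sample matrix of allele-b dosages
#' (0, 1, 2 or `NA`). On the X chromosome, males outside the pseudo-autosomal
#' region (PAR) are hemizygous, so after [clean_hemizygous()] their legal
#' dosages outside the PAR are 0, 2 or `NA` only.
#'
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_bp` (1-based,
#'   strictly increasing within chromosome), `allele_a`, `allele_b`, and
#'   optionally `ancestral` (`"a"`, `"b"` or `"unknown"`), `in_par` (logical),
#'   `gentrain`, `gencall` (array quality scores in `[0, 1]`).
#' @param samples data.frame with columns `sample_id` (unique), `sex`
#'   (`"male"`/`"female"`), `population`, `species` (`"focal"`/`"outgroup"`).
#' @param calls integer matrix, SNPs in rows, samples in columns; allele-b
#'   dosage with `NA` for missing.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(map, samples, calls) {
  map <- as_snp_map(map)
  samples <- as_sample_info(samples)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(map) || ncol(calls) != nrow(samples)) {
    stop("calls must be n_snps x n_samples (", nrow(map), " x ", nrow(samples), ")")
  }
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(calls) <- list(map$snp_id, samples$sample_id)
  structure(list(map = map, samples = samples, calls = calls),
            class = "genotype_matrix")
}

as_snp_map <- function(map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos_bp", "allele_a", "allele_b")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("snp map missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  if (any(map$allele_a == map$allele_b)) stop("allele_a and allele_b must differ")
  map$pos_bp <- as.integer(map$pos_bp)
  if (any(map$pos_bp < 1L)) stop("pos_bp must be >= 1 (1-based)")
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      warning("snp map not strictly sorted by position; sorting")
      o <- order(map$chrom, map$pos_bp)
      map <- map[o, , drop = FALSE]
      break
    }
  }
  if (is.null(map$ancestral)) map$ancestral <- "unknown"
  if (is.null(map$in_par)) map$in_par <- FALSE
  if (is.null(map$gentrain)) map$gentrain <- NA_real_
  if (is.null(map$gencall)) map$gencall <- NA_real_
  rownames(map) <- NULL
  map
}

as_sample_info <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "population", "species")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (!all(samples$sex %in% c("male", "female"))) stop("sex must be male/female")
  if (!all(samples$species %in% c("focal", "outgroup"))) {
    stop("species must be focal/outgroup")
  }
  rownames(samples) <- NULL
  samples
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$map), "SNPs x", nrow(x$samples), "samples\n")
  cat("  males:", sum(x$samples$sex == "male"),
      " females:", sum(x$samples$sex == "female"),
      " outgroup:", sum(x$samples$species == "outgroup"), "\n")
  cat("  PAR SNPs flagged:", sum(x$map$in_par), "\n")
  invisible(x)
}

#' Read a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `sex`, `population`, `species`.
#'
#' @param path path to TSV.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  as_sample_info(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#"))
}

#' Read genotypes from PLINK binary or VCF
#'
#' Calls are encoded as allele-b dosage (PLINK A2 / VCF ALT count); missing
#' calls are preserved as `NA` and SNPs are returned sorted by position.
#' Non-biallelic VCF records are skipped with a warning.
#'
#' @param path for `"plink-bed"`, the path prefix of the `.bed/.bim/.fam`
#'   trio (or the `.bed` file itself); for `"vcf"`, the VCF file.
#' @param format `"plink-bed"` or `"vcf"`.
#' @param sample_sheet data.frame as from [read_sample_sheet()] (or a path to
#'   one) mapping every genotyped sample to sex/population/species.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink-bed", "vcf"), sample_sheet) {
  format <- match.arg(format)
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  sample_sheet <- as_sample_info(sample_sheet)
  raw <- if (format == "plink-bed") read_plink_raw(path) else read_vcf_raw(path)
  idx <- match(raw$sample_ids, sample_sheet$sample_id)
  if (anyNA(idx)) {
    stop("sample ids absent from sample sheet: ",
         paste(head(raw$sample_ids[is.na(idx)], 5), collapse = ", "))
  }
  genotype_matrix(raw$map, sample_sheet[idx, , drop = FALSE], raw$calls)
}

read_plink_raw <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos_bp", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n_snp <- nrow(bim)
  n_samp <- nrow(fam)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK v1.00 .bed file")
  }
  bps <- ceiling(n_samp / 4)
  bytes <- readBin(con, "raw", n_snp * bps)
  if (length(bytes) < n_snp * bps) stop("truncated .bed file")
  ## 2-bit codes per sample: 00 hom a1, 01 missing, 10 het, 11 hom a2
  m <- matrix(as.integer(bytes), nrow = bps)
  calls <- matrix(NA_integer_, nrow = n_snp, ncol = n_samp)
  code <- matrix(NA_integer_, nrow = bps * 4, ncol = n_snp)
  for (shift in 0:3) {
    code[seq(shift + 1, by = 4, length.out = bps), ] <-
      (m %/% 4L^shift) %% 4L
  }
  code <- t(code[seq_len(n_samp), , drop = FALSE])
  calls[code == 0L] <- 0L   # two copies of a1
  calls[code == 2L] <- 1L
  calls[code == 3L] <- 2L   # two copies of a2
  map <- data.frame(snp_id = bim$snp_id, chrom = as.character(bim$chrom),
                    pos_bp = bim$pos_bp, allele_a = bim$a1, allele_b = bim$a2,
                    stringsAsFactors = FALSE)
  o <- order(map$chrom, map$pos_bp)
  list(map = map[o, , drop = FALSE], calls = calls[o, , drop = FALSE],
       sample_ids = as.character(fam[[2]]))
}

read_vcf_raw <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) as.data.frame(fix, stringsAsFactors = FALSE) else
    as.data.frame(t(fix), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi)) {
    warning(sum(multi), " non-biallelic VCF record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ## dosage = count of ALT alleles; haploid calls ("0"/"1") count once
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d1 <- ifelse(a1 == "1", 1L, ifelse(a1 == "0", 0L, NA_integer_))
  d2 <- ifelse(a2 == "1", 1L, ifelse(a2 == "0", 0L, NA_integer_))
  haploid <- nchar(gt) == 1 & !is.na(gt)
  calls <- d1 + d2
  calls[haploid] <- ifelse(d1[haploid] == 1L, 2L, 0L)
  calls[is.na(d1)] <- NA_integer_
  calls <- matrix(as.integer(calls), nrow = nrow(fix))
  map <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                    pos_bp = as.integer(fix$POS),
                    allele_a = fix$REF, allele_b = fix$ALT,
                    stringsAsFactors = FALSE)
  noid <- is.na(map$snp_id) | map$snp_id == "."
  map$snp_id[noid] <- paste0(map$chrom[noid], "_", map$pos_bp[noid])
  o <- order(map$chrom, map$pos_bp)
  list(map = map[o, , drop = FALSE], calls = calls[o, , drop = FALSE],
       sample_ids = colnames(gt))
}

#' Write genotypes to PLINK binary or VCF
#'
#' @param gm a [genotype_matrix()].
#' @param path output prefix (PLINK) or file path (VCF).
#' @param format `"plink-bed"` or `"vcf"`.
#' @return The path(s) written, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("plink-bed", "vcf")) {
  format <- match.arg(format)
  if (format == "plink-bed") write_plink_raw(gm, path) else write_vcf_raw(gm, path)
}

write_plink_raw <- function(gm, prefix) {
  map <- gm$map
  bim <- data.frame(map$chrom, map$snp_id, 0, map$pos_bp,
                    map$allele_a, map$allele_b)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  s <- gm$samples
  fam <- data.frame(s$population, s$sample_id, 0, 0,
                    ifelse(s$sex == "male", 1, 2), -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n_samp <- nrow(s)
  bps <- ceiling(n_samp / 4)
  code <- matrix(1L, nrow = bps * 4, ncol = nrow(map))  # 01 = missing
  d <- t(gm$calls)
  cd <- matrix(1L, nrow = n_samp, ncol = nrow(map))
  cd[d == 0L] <- 0L
  cd[d == 1L] <- 2L
  cd[d == 2L] <- 3L
  cd[is.na(d)] <- 1L
  code[seq_len(n_samp), ] <- cd
  bytes <- matrix(0L, nrow = bps, ncol = nrow(map))
  for (shift in 0:3) {
    bytes <- bytes + code[seq(shift + 1, by = 4, length.out = bps), , drop = FALSE] * 4L^shift
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

write_vcf_raw <- function(gm, path, phased = NULL) {
  map <- gm$map
  s <- gm$samples
  gt <- matrix("./.", nrow = nrow(map), ncol = nrow(s))
  gt[gm$calls == 0L] <- "0/0"
  gt[gm$calls == 1L] <- "0/1"
  gt[gm$calls == 2L] <- "1/1"
  ## hemizygous male calls outside the PAR are emitted as haploid GTs
  male <- s$sex == "male"
  if (any(male) && any(!map$in_par)) {
    hz <- which(!map$in_par)
    for (j in which(male)) {
      gj <- gt[hz, j]
      gj[gm$calls[hz, j] %in% 0L] <- "0"
      gj[gm$calls[hz, j] %in% 2L] <- "1"
      gj[is.na(gm$calls[hz, j])] <- "."
      gt[hz, j] <- gj
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", s$sample_id), collapse = "\t")), con)
  body <- cbind(map$chrom, map$pos_bp, map$snp_id, map$allele_a, map$allele_b,
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Per-SNP observed heterozygosity by sex
#'
#' For the requested sex, the fraction of non-missing calls that are
#' heterozygous (dosage 1). SNPs where every call of that sex is missing get
#' `NA` (undefined, not zero).
#'
#' @param gm a [genotype_matrix()].
#' @param sex `"male"` or `"female"`.
#' @return data.frame with `snp_id`, `pos_bp`, `n_called`, `h_obs`.
#' @export
observed_heterozygosity <- function(gm, sex = c("male", "female")) {
  sex <- match.arg(sex)
  keep <- gm$samples$sex == sex
  if (!any(keep)) stop("no samples of sex ", sex)
  calls <- gm$calls[, keep, drop = FALSE]
  n_called <- rowSums(!is.na(calls))
  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  h <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  data.frame(snp_id = gm$map$snp_id, pos_bp = gm$map$pos_bp,
             n_called = n_called, h_obs = h, stringsAsFactors = FALSE)
}

#' Localize the pseudo-autosomal boundary from male heterozygosity
#'
#' Males are diploid in the PAR and hemizygous beyond it, so their observed
#' heterozygosity collapses to ~0 at the PAR boundary. The boundary is placed
#' at the last SNP before the first position where the mean male H_O over the
#' window of the next `window_snps` SNPs falls below `het_floor` and stays
#' below it for the remainder of the chromosome (isolated mis-genotyped SNPs
#' are absorbed by the window mean). SNPs beyond the boundary at which any
#' male is heterozygous are reported as mis-genotyped.
#'
#' @param gm a [genotype_matrix()] with at least 10 males.
#' @param window_snps window size in SNPs for the running mean.
#' @param het_floor heterozygosity level below which males are called
#'   hemizygous.
#' @param het_diploid per-SNP H_O level above which a single SNP counts as
#'   clearly diploid when refining the boundary inside the transition
#'   window (male H_O in the PAR sits near 0.3; isolated genotyping
#'   artifacts far below 0.1).
#' @return list with `par_boundary_bp` (end of the PAR, 1-based; 0 when no
#'   PAR is present), `n_par_snps`, `mis_genotyped_snp_ids`, and the male
#'   `het_profile`.
#' @export
detect_par <- function(gm, window_snps = 50, het_floor = 0.01,
                       het_diploid = 0.1) {
  if (sum(gm$samples$sex == "male") < 10) stop("detect_par needs >= 10 males")
  hp <- observed_heterozygosity(gm, "male")
  h <- hp$h_obs
  h[is.na(h)] <- 0
  n <- length(h)
  if (n < window_snps) stop("fewer SNPs than window_snps")
  ## forward-window running mean: m[i] = mean over SNPs i .. i+window-1
  cs <- cumsum(c(0, h))
  nwin <- n - window_snps + 1
  m <- (cs[(window_snps + 1):(n + 1)] - cs[1:nwin]) / window_snps
  low <- m < het_floor
  ## first window start from which every window stays below the floor
  stays <- rev(cumprod(rev(low))) > 0
  if (!any(stays)) {
    warning("no hemizygous transition found; boundary placed at chromosome end")
    first_low <- n + 1L
  } else {
    first_low <- which(stays)[1]
  }
  ## refine within the transition window: the boundary SNP is the last
  ## clearly diploid SNP (per-SNP H_O at or above het_diploid) at or before
  ## the first all-low window's end. This pins the boundary to the final
  ## truly diploid SNP instead of one window-mean step early, while isolated
  ## mis-genotyped SNPs (low but nonzero H_O) cannot drag it rightwards.
  hi <- which(h >= het_diploid & seq_len(n) <= min(n, first_low + window_snps - 1L))
  n_par <- if (length(hi)) max(hi) else max(0L, first_low - 1L)
  if (n_par == 0L) {
    warning("male heterozygosity low from the first SNP; no PAR detected")
    boundary <- 0L
  } else {
    boundary <- gm$map$pos_bp[n_par]
  }
  hemi <- seq_len(n) > n_par
  mis <- gm$map$snp_id[hemi & hp$h_obs > 0 & !is.na(hp$h_obs)]
  list(par_boundary_bp = boundary, n_par_snps = n_par,
       mis_genotyped_snp_ids = mis, het_profile = hp)
}

#' Flag the PAR and clean hemizygous male calls
#'
#' Applies a PAR boundary to the map (`in_par` for SNPs at or before
#' `boundary_bp`), drops SNPs beyond the boundary at which one or more males
#' are heterozygous (mis-genotyped), and sets any residual male heterozygous
#' call outside the PAR to missing. After this, no male carries dosage 1 at a
#' non-PAR SNP.
#'
#' @param gm a [genotype_matrix()].
#' @param boundary_bp PAR boundary from [detect_par()].
#' @param drop_misgenotyped drop SNPs with male heterozygous calls beyond the
#'   boundary entirely (default), rather than only recoding the calls.
#' @return Cleaned [genotype_matrix()] with attribute `"cleaning_report"`.
#' @export
clean_hemizygous <- function(gm, boundary_bp, drop_misgenotyped = TRUE) {
  gm$map$in_par <- gm$map$pos_bp <= boundary_bp
  male <- gm$samples$sex == "male"
  hemi <- !gm$map$in_par
  het_snp <- hemi & rowSums(gm$calls[, male, drop = FALSE] == 1L, na.rm = TRUE) > 0
  dropped <- gm$map$snp_id[het_snp]
  if (drop_misgenotyped && any(het_snp)) {
    gm$map <- gm$map[!het_snp, , drop = FALSE]
    gm$calls <- gm$calls[!het_snp, , drop = FALSE]
    hemi <- !gm$map$in_par
  }
  n_recoded <- 0L
  if (any(hemi) && any(male)) {
    sub <- gm$calls[hemi, male, drop = FALSE]
    n_recoded <- sum(sub == 1L, na.rm = TRUE)
    sub[sub == 1L] <- NA_integer_
    gm$calls[hemi, male] <- sub
  }
  attr(gm, "cleaning_report") <- list(mis_genotyped_dropped = dropped,
                                      male_het_calls_set_missing = n_recoded)
  gm
}

## Mid-p Hardy-Weinberg exact test over diploid genotype counts.
## Enumerates the exact conditional distribution of heterozygote counts.
hwe_midp <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  het_vals <- seq(rare %% 2, rare, by = 2)
  ## log P(n_ab = h | allele counts) up to a constant
  logp <- lgamma(n + 1) - lgamma((n_a - het_vals) / 2 + 1) -
    lgamma(het_vals + 1) - lgamma((n_b - het_vals) / 2 + 1) +
    het_vals * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(het_vals == n_ab)
  if (length(obs) == 0) return(NA_real_)  # impossible configuration
  pv <- sum(p[p <= p[obs]]) - 0.5 * p[obs]
  min(1, max(pv, 0))
}

#' Quality-control filter for SNPs and individuals
#'
#' Removes SNPs failing array quality scores (when metadata are present), call
#' rate, or a Hardy-Weinberg mid-p exact test, then individuals with low call
#' rate over the retained SNPs. The HWE test uses diploid calls only: females
#' outside the PAR, all samples inside the PAR; exclusion uses strict `<`
#' (`p == hwe_p` is retained). Quality criteria are skipped with a message
#' when the map carries no scores.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_call_rate minimum SNP call rate.
#' @param hwe_p Hardy-Weinberg exclusion level (strict `<`).
#' @param ind_call_rate minimum individual call rate.
#' @param gentrain minimum GenTrain score (strict `<` drops).
#' @param gencall minimum GenCall score (`<=` drops).
#' @return Filtered [genotype_matrix()] with attribute `"qc_report"`, a
#'   data.frame of dropped ids and reasons.
#' @export
qc_filter <- function(gm, snp_call_rate = 0.90, hwe_p = 1e-7,
                      ind_call_rate = 0.95, gentrain = 0.4, gencall = 0.8) {
  map <- gm$map
  calls <- gm$calls
  n_samp <- ncol(calls)
  reasons <- rep(NA_character_, nrow(map))
  cr <- rowSums(!is.na(calls)) / n_samp
  fail_cr <- cr < snp_call_rate
  reasons[fail_cr] <- "call_rate"
  if (all(is.na(map$gentrain)) && all(is.na(map$gencall))) {
    message("no array quality scores in map; GenTrain/GenCall filters skipped")
  } else {
    fail_gt <- !is.na(map$gentrain) & map$gentrain < gentrain
    fail_gc <- !is.na(map$gencall) & map$gencall <= gencall
    reasons[is.na(reasons) & fail_gt] <- "gentrain"
    reasons[is.na(reasons) & fail_gc] <- "gencall"
  }
  diploid_female <- gm$samples$sex == "female"
  hwe <- vapply(seq_len(nrow(map)), function(i) {
    cols <- if (map$in_par[i]) rep(TRUE, n_samp) else diploid_female
    g <- calls[i, cols]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_midp(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  fail_hwe <- !is.na(hwe) & hwe < hwe_p
  reasons[is.na(reasons) & fail_hwe] <- "hwe"
  keep_snp <- is.na(reasons)
  if (!any(keep_snp)) warning("qc_filter removed every SNP")
  calls2 <- calls[keep_snp, , drop = FALSE]
  ind_cr <- colSums(!is.na(calls2)) / max(1, nrow(calls2))
  keep_ind <- ind_cr >= ind_call_rate
  if (!any(keep_ind)) warning("qc_filter removed every individual")
  out <- gm
  out$map <- map[keep_snp, , drop = FALSE]
  out$samples <- gm$samples[keep_ind, , drop = FALSE]
  out$calls <- calls2[, keep_ind, drop = FALSE]
  rownames(out$map) <- rownames(out$samples) <- NULL
  attr(out, "qc_report") <- rbind(
    data.frame(id = map$snp_id[!keep_snp],
               type = rep("snp", sum(!keep_snp)),
               reason = reasons[!keep_snp], stringsAsFactors = FALSE),
    data.frame(id = gm$samples$sample_id[!keep_ind],
               type = rep("individual", sum(!keep_ind)),
               reason = rep("ind_call_rate", sum(!keep_ind)),
               stringsAsFactors = FALSE))
  out
}

#' Assign ancestral alleles from outgroup genotypes
#'
#' The ancestral state at each SNP is the majority allele among outgroup
#' allele copies (diploid calls contribute two copies, hemizygous male calls
#' outside the PAR one). Ties and all-missing SNPs are left `"unknown"`.
#'
#' @param gm a [genotype_matrix()] containing at least one outgroup sample.
#' @return The SNP map with the `ancestral` column filled
#'   (`"a"`/`"b"`/`"unknown"`).
#' @export
assign_ancestral <- function(gm) {
  og <- gm$samples$species == "outgroup"
  if (!any(og)) stop("no outgroup samples present")
  calls <- gm$calls[, og, drop = FALSE]
  male <- gm$samples$sex[og] == "male"
  hemi <- !gm$map$in_par
  ## allele copies: diploid row of weights 2, hemizygous male non-PAR weight 1
  w <- matrix(2, nrow = nrow(calls), ncol = ncol(calls))
  if (any(male) && any(hemi)) w[hemi, male] <- 1
  bcopies <- (gm$calls[, og, drop = FALSE] / 2) * w
  total <- w
  total[is.na(calls)] <- 0
  bcopies[is.na(calls)] <- 0
  nb <- rowSums(bcopies)
  na_ <- rowSums(total) - nb
  anc <- ifelse(rowSums(total) == 0, "unknown",
                ifelse(na_ > nb, "a", ifelse(nb > na_, "b", "unknown")))
  map <- gm$map
  map$ancestral <- anc
  map
}

#' Recode haplotypes to ancestral/derived states
#'
#' Flips haplotype columns at SNPs whose ancestral allele is `b`, so that 0
#' always means ancestral and 1 derived. An involution: applying it twice
#' returns the input. SNPs with unknown ancestral state are left untouched
#' and flagged in the `"unknown_ancestral"` attribute.
#'
#' @param haps a [phased_haplotypes()] object (allele-b coding).
#' @param snpmap SNP map with `ancestral` filled, rows matching `haps` columns.
#' @return The recoded [phased_haplotypes()].
#' @export
recode_ancestral <- function(haps, snpmap) {
  if (nrow(snpmap) != ncol(haps$haps)) stop("snpmap does not match haplotypes")
  flip <- snpmap$ancestral == "b"
  if (any(flip)) haps$haps[, flip] <- 1L - haps$haps[, flip]
  attr(haps, "unknown_ancestral") <- which(snpmap$ancestral == "unknown")
  haps$coding <- if (identical(haps$coding, "ancestral")) "allele_b" else "ancestral"
  haps
}
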