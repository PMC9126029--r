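## Pipeline orchestration: QC -> PAR -> (eROHi | iHS/nSL | HRiD) -> signals
## -> haplotype networks, with TSV/BED outputs and a run log. All TSV
## coordinates are 1-based closed; BED files are 0-based half-open.

#' Build a run configuration
#'
#' Collects every module threshold with its default; unknown names are an
#' error. The configuration is echoed verbatim into the run log so a run is
#' reproducible from config + inputs.
#'
#' @param ... overrides for: `snp_call_rate`, `hwe_p`, `ind_call_rate`,
#'   `gentrain`, `gencall`, `par_window_snps`, `par_het_floor`,
#'   `erohi_threshold` (NA = derive from simpleM), `erohi_min_consecutive`,
#'   `maf_floor`, `bin_width`, `win_bp`, `slide_bp`, `outlier_neglogp`,
#'   `prop_threshold`, `hrid_size`, `hrid_step`, `hrid_threshold`,
#'   `hrid_max_missing`, `net_max_mutations`, `seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    snp_call_rate = 0.90, hwe_p = 1e-7, ind_call_rate = 0.95,
    gentrain = 0.4, gencall = 0.8,
    par_window_snps = 50, par_het_floor = 0.01,
    erohi_threshold = 3.3, erohi_min_consecutive = 2,
    maf_floor = 0.05, bin_width = 0.025,
    win_bp = 500000, slide_bp = 100000,
    outlier_neglogp = 2.0, prop_threshold = 0.10,
    hrid_size = 70, hrid_step = 35, hrid_threshold = 3.3,
    hrid_max_missing = 0,
    net_max_mutations = 3,
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Run the full selection-signature scan
#'
#' Stage order: QC filtering, PAR localization and hemizygous clean-up,
#' ancestral-allele assignment from the outgroup, then the three scans —
#' eROHi on females, iHS/nSL on phased haplotypes (when supplied), HRiD on
#' hemizygous male haplotypes — followed by signal calling and, when
#' requested, a median-joining network per HRiD signal. Results are written
#' as TSV/BED under `out_prefix` when given and returned as a bundle.
#'
#' @param gm a [genotype_matrix()] (raw; QC is applied here).
#' @param config a [run_config()].
#' @param haps optional [phased_haplotypes()] for the iHS/nSL stage (phased
#'   input; the package does no statistical phasing). Columns must match the
#'   post-QC map; SNPs dropped by QC are removed by id.
#' @param out_prefix optional output path prefix.
#' @param networks build a haplotype network per HRiD signal (needs outgroup
#'   males).
#' @return list with `gm` (clean), `par`, `erohi`, `ihs`, `nsl`, `hrid`,
#'   `networks`, `log`.
#' @export
run_scan <- function(gm, config = run_config(), haps = NULL,
                     out_prefix = NULL, networks = TRUE) {
  log <- c(sprintf("xselscan run | seed=%d", config$seed),
           paste0("config: ", paste(sprintf("%s=%s", names(config),
                                            vapply(config, format, "")),
                                    collapse = " ")))
  set.seed(config$seed)
  ## -- QC ------------------------------------------------------------
  gm_qc <- qc_filter(gm, snp_call_rate = config$snp_call_rate,
                     hwe_p = config$hwe_p, ind_call_rate = config$ind_call_rate,
                     gentrain = config$gentrain, gencall = config$gencall)
  qc_rep <- attr(gm_qc, "qc_report")
  log <- c(log, sprintf("qc: %d SNPs and %d individuals dropped",
                        sum(qc_rep$type == "snp"),
                        sum(qc_rep$type == "individual")))
  ## -- PAR ------------------------------------------------------------
  par <- detect_par(gm_qc, window_snps = config$par_window_snps,
                    het_floor = config$par_het_floor)
  gm_clean <- clean_hemizygous(gm_qc, par$par_boundary_bp)
  log <- c(log, sprintf("par: boundary %d bp, %d PAR SNPs, %d mis-genotyped dropped",
                        par$par_boundary_bp, par$n_par_snps,
                        length(attr(gm_clean, "cleaning_report")$mis_genotyped_dropped)))
  ## -- ancestral alleles ----------------------------------------------
  if (any(gm_clean$samples$species == "outgroup")) {
    gm_clean$map <- assign_ancestral(gm_clean)
    log <- c(log, sprintf("ancestral: %d SNPs unresolved",
                          sum(gm_clean$map$ancestral == "unknown")))
  } else {
    log <- c(log, "ancestral: no outgroup; skipped")
  }
  ## -- eROHi on females ------------------------------------------------
  erohi <- NULL
  fem <- gm_clean$samples$sex == "female" & gm_clean$samples$species == "focal"
  if (sum(fem) >= 2) {
    gm_f <- gm_clean
    gm_f$samples <- gm_clean$samples[fem, , drop = FALSE]
    gm_f$calls <- gm_clean$calls[, fem, drop = FALSE]
    segs <- call_roh(gm_f)
    freqs <- snp_roh_frequency(segs, gm_clean$map, sum(fem))
    thr <- config$erohi_threshold
    sm <- NULL
    if (is.na(thr)) {
      sm <- simple_m(gm_f)
      thr <- sm$threshold_neglogp
    }
    erohi <- list(segments = segs, freqs = NULL, signals = NULL,
                  threshold = thr, simple_m = sm)
    if (nrow(segs) > 0 && sd(freqs$frequency) > 0) {
      freqs <- roh_neglogp(freqs)
      erohi$freqs <- freqs
      erohi$signals <- call_erohi_signals(freqs, threshold = thr,
                                          min_consecutive = config$erohi_min_consecutive)
    } else {
      erohi$freqs <- freqs
      erohi$signals <- call_erohi_signals(
        data.frame(pos_bp = freqs$pos_bp, neglogp = rep(0, nrow(freqs))),
        threshold = thr)
    }
    log <- c(log, sprintf("erohi: %d segments, %d signals", nrow(segs),
                          nrow(erohi$signals)))
  } else log <- c(log, "erohi: <2 females; skipped")
  ## -- iHS / nSL on phased haplotypes ---------------------------------
  ihs <- nsl <- NULL
  if (!is.null(haps)) {
    keep <- haps$snp_id %in% gm_clean$map$snp_id
    hp <- haps
    hp$haps <- hp$haps[, keep, drop = FALSE]
    hp$pos_bp <- hp$pos_bp[keep]
    hp$snp_id <- hp$snp_id[keep]
    map_idx <- match(hp$snp_id, gm_clean$map$snp_id)
    submap <- gm_clean$map[map_idx, , drop = FALSE]
    if (hp$coding != "ancestral") hp <- recode_ancestral(hp, submap)
    for (stat in c("ihs", "nsl")) {
      raw <- if (stat == "ihs") ihs_raw(hp, submap, maf_floor = config$maf_floor)
             else nsl_raw(hp, submap, maf_floor = config$maf_floor)
      std <- bin_standardize(raw, bin_width = config$bin_width)
      win <- window_outlier_scan(std, win_bp = config$win_bp,
                                 slide_bp = config$slide_bp,
                                 outlier_neglogp = config$outlier_neglogp,
                                 prop_threshold = config$prop_threshold)
      res <- list(snps = std, windows = win)
      if (stat == "ihs") ihs <- res else nsl <- res
      log <- c(log, sprintf("%s: %d scored SNPs, %d significant windows",
                            stat, sum(!is.na(std$z)), nrow(win)))
    }
  } else log <- c(log, "ihs/nsl: no phased haplotypes supplied; skipped")
  ## -- HRiD on hemizygous males ----------------------------------------
  hrid <- NULL
  males <- sum(gm_clean$samples$sex == "male" & gm_clean$samples$species == "focal")
  if (males >= 2 && sum(!gm_clean$map$in_par) >= config$hrid_size) {
    mh <- hemizygous_haplotypes(gm_clean, species = "focal")
    hrid <- hrid_scan(mh, size = config$hrid_size, step = config$hrid_step,
                      threshold = config$hrid_threshold,
                      max_missing_frac = config$hrid_max_missing)
    log <- c(log, sprintf("hrid: %d windows, %d signals",
                          nrow(hrid$windows), nrow(hrid$signals)))
  } else log <- c(log, "hrid: skipped (needs males and a full window)")
  ## -- networks per HRiD signal ----------------------------------------
  nets <- list()
  og_males <- sum(gm_clean$samples$sex == "male" &
                    gm_clean$samples$species == "outgroup")
  if (networks && !is.null(hrid) && nrow(hrid$signals) > 0 && og_males > 0) {
    mh_all <- hemizygous_haplotypes(gm_clean, species = "both")
    for (k in seq_len(nrow(hrid$signals))) {
      idx <- as.integer(strsplit(hrid$signals$member_indices[k], ",")[[1]])
      first <- min(hrid$windows$first_snp_idx[hrid$windows$index %in% idx])
      last <- max(hrid$windows$last_snp_idx[hrid$windows$index %in% idx])
      uh <- tryCatch(unique_haplotypes(mh_all, window = c(first, last)),
                     error = function(e) NULL, warning = function(w) {
                       suppressWarnings(unique_haplotypes(mh_all,
                                                          window = c(first, last)))
                     })
      if (is.null(uh)) next
      net <- median_joining_network(uh)
      grp <- favourable_group(net, max_mutations = config$net_max_mutations)
      origin <- tryCatch(classify_origin(net, grp), error = function(e) NA)
      nets[[k]] <- list(signal = hrid$signals[k, ], network = net,
                        group = grp, origin = origin)
    }
    log <- c(log, sprintf("networks: %d built", length(nets)))
  }
  bundle <- list(gm = gm_clean, par = par, erohi = erohi, ihs = ihs,
                 nsl = nsl, hrid = hrid, networks = nets, log = log)
  if (!is.null(out_prefix)) write_bundle(bundle, out_prefix, config)
  bundle
}

write_bundle <- function(bundle, prefix, config) {
  coord_note <- "coordinates 1-based closed [start_bp, end_bp]"
  qc_rep <- attr(bundle$gm, "qc_report")
  if (!is.null(qc_rep)) write_tsv(qc_rep, paste0(prefix, "_qc_report.tsv"))
  write_tsv(data.frame(par_boundary_bp = bundle$par$par_boundary_bp,
                       n_par_snps = bundle$par$n_par_snps,
                       mis_genotyped = paste(bundle$par$mis_genotyped_snp_ids,
                                             collapse = ",")),
            paste0(prefix, "_par_report.tsv"))
  if (!is.null(bundle$erohi)) {
    write_tsv(bundle$erohi$segments, paste0(prefix, "_roh_segments.tsv"),
              coord_note)
    write_tsv(bundle$erohi$freqs, paste0(prefix, "_roh_freq.tsv"))
    write_tsv(bundle$erohi$signals, paste0(prefix, "_erohi_signals.tsv"),
              coord_note)
    if (nrow(bundle$erohi$signals) > 0) {
      write_tsv(to_bed("X", bundle$erohi$signals$start_bp,
                       bundle$erohi$signals$end_bp,
                       name = sprintf("eROHi_%d", seq_len(nrow(bundle$erohi$signals)))),
                paste0(prefix, "_erohi_signals.bed"),
                "BED: 0-based half-open")
    }
  }
  for (stat in c("ihs", "nsl")) {
    res <- bundle[[stat]]
    if (is.null(res)) next
    write_tsv(res$snps, paste0(prefix, "_", stat, "_snps.tsv"))
    write_tsv(res$windows, paste0(prefix, "_", stat, "_windows.tsv"), coord_note)
  }
  if (!is.null(bundle$hrid)) {
    write_tsv(bundle$hrid$windows, paste0(prefix, "_hrid_windows.tsv"),
              coord_note)
    write_tsv(bundle$hrid$signals, paste0(prefix, "_hrid_signals.tsv"),
              coord_note)
    if (nrow(bundle$hrid$signals) > 0) {
      write_tsv(to_bed("X", bundle$hrid$signals$start_bp,
                       bundle$hrid$signals$end_bp,
                       name = sprintf("HRiD_%d", seq_len(nrow(bundle$hrid$signals)))),
                paste0(prefix, "_hrid_signals.bed"), "BED: 0-based half-open")
    }
  }
  for (k in seq_along(bundle$networks)) {
    if (!is.null(bundle$networks[[k]])) {
      write_haplonet(bundle$networks[[k]]$network,
                     sprintf("%s_signal%d", prefix, k))
    }
  }
  mh <- manhattan_export(bundle)
  write_tsv(mh, paste0(prefix, "_manhattan.tsv"))
  writeLines(bundle$log, paste0(prefix, "_run_log.txt"))
  invisible(prefix)
}

#' Export Manhattan-plot data across scan tracks
#'
#' One row per SNP (eROHi, iHS, nSL tracks) or window midpoint (HRiD track)
#' with its -log10 p, significance flag, and PAR membership (PAR SNPs are
#' plotted in their own colour).
#'
#' @param bundle result of [run_scan()].
#' @return data.frame with `pos_bp`, `neglogp`, `track`, `significant`,
#'   `in_par`.
#' @export
manhattan_export <- function(bundle) {
  rows <- list()
  par_flag <- function(pos) {
    pos <= bundle$par$par_boundary_bp
  }
  if (!is.null(bundle$erohi) && !is.null(bundle$erohi$freqs) &&
      "neglogp" %in% names(bundle$erohi$freqs)) {
    f <- bundle$erohi$freqs
    sig_pos <- logical(nrow(f))
    for (k in seq_len(nrow(bundle$erohi$signals))) {
      sig_pos <- sig_pos | (f$pos_bp >= bundle$erohi$signals$start_bp[k] &
                              f$pos_bp <= bundle$erohi$signals$end_bp[k])
    }
    rows[[length(rows) + 1]] <- data.frame(
      pos_bp = f$pos_bp, neglogp = f$neglogp, track = "erohi",
      significant = sig_pos & f$neglogp >= bundle$erohi$threshold,
      in_par = par_flag(f$pos_bp))
  }
  for (stat in c("ihs", "nsl")) {
    res <- bundle[[stat]]
    if (is.null(res)) next
    s <- res$snps
    sig_pos <- logical(nrow(s))
    for (k in seq_len(nrow(res$windows))) {
      sig_pos <- sig_pos | (s$pos_bp >= res$windows$start_bp[k] &
                              s$pos_bp <= res$windows$end_bp[k])
    }
    rows[[length(rows) + 1]] <- data.frame(
      pos_bp = s$pos_bp, neglogp = s$neglogp, track = stat,
      significant = sig_pos, in_par = par_flag(s$pos_bp))
  }
  if (!is.null(bundle$hrid)) {
    w <- bundle$hrid$windows
    mid <- (w$start_bp + w$end_bp) %/% 2
    rows[[length(rows) + 1]] <- data.frame(
      pos_bp = mid, neglogp = w$neglogp, track = "hrid",
      significant = w$significant, in_par = par_flag(mid))
  }
  if (length(rows) == 0) {
    return(data.frame(pos_bp = integer(), neglogp = numeric(),
                      track = character(), significant = logical(),
                      in_par = logical()))
  }
  do.call(rbind, rows)
}
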