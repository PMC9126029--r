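## Founder-mosaic simulator for X-chromosome SNP-array data: PAR +
## hemizygous region, focal males/females and a small outgroup, neutral
## haplotype diversity with recombination-style founder switching, and
## injectable hard sweeps. Every output is reproducible from the seed.

#' Simulation parameters
#'
#' Defaults emulate an X-chromosome array panel: ~2,000 SNPs of which the
#' first 150 form the PAR, 100 focal hemizygous males, 101 diploid females,
#' and a 10-animal outgroup (5 males, 5 females). Haplotypes are mosaics of
#' `n_founders` founder haplotypes derived from an all-ancestral root by
#' independent per-SNP mutation; the founder index switches at each SNP
#' boundary with probability `recomb_rate`. Genotyping error (0.25%, the HD
#' chip rate) and missingness are applied last.
#'
#' @param n_snps total SNPs (default 2000).
#' @param par_snps leading SNPs forming the PAR (default 150).
#' @param n_males,n_females focal sample sizes (defaults 100 / 101).
#' @param n_outgroup_males,n_outgroup_females outgroup sizes (defaults 5 / 5).
#' @param n_founders founder haplotype pool size K (default 30).
#' @param founder_mut_rate per-SNP mutation probability from the root when
#'   drawing founders (default 0.3).
#' @param recomb_rate founder switch probability per SNP boundary
#'   (default 0.02).
#' @param missing_rate per-call missingness (default 0.002).
#' @param error_rate per-call symmetric genotyping error (default 0.0025).
#' @param dirichlet_conc concentration of the Dirichlet founder frequencies
#'   (default 1 = flat).
#' @param n_misgenotyped number of non-PAR SNPs given male heterozygous
#'   artifact calls (default 0), for testing mis-genotyping detection.
#' @param sweeps optional data.frame (`snp_start`, `snp_end`, `f_s`,
#'   `origin`) applied before noise, as in [inject_sweep()].
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_snps = 2000, par_snps = 150, n_males = 100,
                       n_females = 101, n_outgroup_males = 5,
                       n_outgroup_females = 5, n_founders = 30,
                       founder_mut_rate = 0.3, recomb_rate = 0.02,
                       missing_rate = 0.002, error_rate = 0.0025,
                       dirichlet_conc = 1, n_misgenotyped = 0,
                       sweeps = NULL) {
  p <- as.list(environment())
  rates <- c(founder_mut_rate, recomb_rate, missing_rate, error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (par_snps >= n_snps) stop("par_snps must be smaller than n_snps")
  if (!is.null(sweeps)) {
    if (any(sweeps$snp_start <= par_snps)) stop("sweep spans must be outside the PAR")
    if (any(sweeps$snp_end > n_snps)) stop("sweep span beyond the map")
    if (any(sweeps$f_s < 0 | sweeps$f_s > 1)) stop("f_s must lie in [0, 1]")
  }
  structure(p, class = "sim_params")
}

## Clean (noise-free) simulation state: founders, positions, sample table,
## and two full haplotypes per sample (males use hap1 outside the PAR).
simulate_core <- function(params, seed) {
  set.seed(seed)
  p <- params
  n <- p$n_snps
  gaps <- round(runif(n, 1000, 13260))  # mean ~7.1 kb spacing
  pos <- cumsum(gaps)
  founders <- matrix(rbinom(p$n_founders * n, 1, p$founder_mut_rate),
                     nrow = p$n_founders)
  freqs <- rgamma(p$n_founders, shape = p$dirichlet_conc)
  freqs <- freqs / sum(freqs)
  root_dist <- rowSums(founders)
  nearest <- order(root_dist)[seq_len(min(5, p$n_founders))]
  samples <- data.frame(
    sample_id = c(sprintf("M%03d", seq_len(p$n_males)),
                  sprintf("F%03d", seq_len(p$n_females)),
                  sprintf("OGM%02d", seq_len(p$n_outgroup_males)),
                  sprintf("OGF%02d", seq_len(p$n_outgroup_females))),
    sex = c(rep("male", p$n_males), rep("female", p$n_females),
            rep("male", p$n_outgroup_males), rep("female", p$n_outgroup_females)),
    population = c(sprintf("breed%d", 1 + (seq_len(p$n_males) - 1) %% 4),
                   sprintf("breed%d", 1 + (seq_len(p$n_females) - 1) %% 4),
                   rep("outgroup", p$n_outgroup_males + p$n_outgroup_females)),
    species = c(rep("focal", p$n_males + p$n_females),
                rep("outgroup", p$n_outgroup_males + p$n_outgroup_females)),
    stringsAsFactors = FALSE)
  n_samp <- nrow(samples)
  mosaic <- function(from_founders, weights) {
    path <- integer(n)
    path[1] <- sample.int(length(weights), 1, prob = weights)
    switch_at <- which(rbinom(n - 1, 1, p$recomb_rate) == 1)
    path <- rep(path[1], n)
    for (s in switch_at) {
      path[(s + 1):n] <- sample.int(length(weights), 1, prob = weights)
    }
    list(hap = from_founders[cbind(path, seq_len(n))], path = path)
  }
  hap1 <- matrix(0L, n_samp, n)
  hap2 <- matrix(0L, n_samp, n)
  paths <- vector("list", n_samp)
  og <- samples$species == "outgroup"
  og_w <- rep(0, p$n_founders)
  og_w[nearest] <- 1 / length(nearest)
  for (i in seq_len(n_samp)) {
    w <- if (og[i]) og_w else freqs
    m1 <- mosaic(founders, w)
    m2 <- mosaic(founders, w)
    hap1[i, ] <- m1$hap
    hap2[i, ] <- m2$hap
    paths[[i]] <- list(h1 = m1$path, h2 = m2$path)
  }
  map <- data.frame(snp_id = sprintf("X_%07d", pos), chrom = "X", pos_bp = pos,
                    allele_a = "A", allele_b = "B", ancestral = "unknown",
                    in_par = seq_len(n) <= p$par_snps,
                    stringsAsFactors = FALSE)
  list(params = p, seed = seed, pos = pos, map = map, samples = samples,
       founders = founders, founder_freqs = freqs, nearest_root = nearest,
       hap1 = hap1, hap2 = hap2, paths = paths,
       par_boundary_bp = pos[p$par_snps], sweeps = list())
}

## Apply a sweep spec to the clean state: within the span, each focal
## haplotype is replaced by the swept haplotype with probability f_s.
apply_sweeps <- function(core, sweeps, seed) {
  set.seed(seed + 101L)
  p <- core$params
  focal <- core$samples$species == "focal"
  male <- core$samples$sex == "male"
  for (r in seq_len(nrow(sweeps))) {
    span <- sweeps$snp_start[r]:sweeps$snp_end[r]
    origin <- sweeps$origin[r]
    if (origin == "ancestral") {
      swept <- core$founders[core$nearest_root[1], span]
    } else {
      ## novel haplotype >= 5 mutations from every founder within the span
      swept <- core$founders[core$nearest_root[1], span]
      repeat {
        flips <- sample.int(length(span), min(length(span), 6))
        cand <- swept
        cand[flips] <- 1L - cand[flips]
        dmin <- min(apply(core$founders[, span, drop = FALSE], 1,
                          function(f) sum(f != cand)))
        if (dmin >= 5) { swept <- cand; break }
      }
    }
    for (i in which(focal)) {
      if (runif(1) < sweeps$f_s[r]) core$hap1[i, span] <- swept
      ## females carry a second sweep-exposed haplotype; male hap2 is
      ## PAR-only and never intersects a (non-PAR) sweep span
      if (!male[i] && runif(1) < sweeps$f_s[r]) core$hap2[i, span] <- swept
    }
    core$sweeps[[length(core$sweeps) + 1]] <-
      list(snp_start = sweeps$snp_start[r], snp_end = sweeps$snp_end[r],
           start_bp = core$pos[sweeps$snp_start[r]],
           end_bp = core$pos[sweeps$snp_end[r]],
           f_s = sweeps$f_s[r], origin = origin, swept_hap = swept)
  }
  core
}

## Dosage assembly plus missingness and symmetric genotyping error.
finalize_genotypes <- function(core) {
  set.seed(core$seed + 202L)
  p <- core$params
  n <- p$n_snps
  samples <- core$samples
  male <- samples$sex == "male"
  par <- seq_len(n) <= p$par_snps
  dos <- t(core$hap1 + core$hap2)  # SNPs x samples
  if (any(male)) {
    dos[!par, male] <- 2L * t(core$hap1[male, !par, drop = FALSE])
  }
  clean <- dos
  if (p$error_rate > 0) {
    err <- matrix(runif(length(dos)) < p$error_rate, nrow = nrow(dos))
    half <- matrix(runif(length(dos)) < 0.5, nrow = nrow(dos))
    diploid <- matrix(TRUE, n, nrow(samples))
    diploid[!par, male] <- FALSE
    flip <- function(d, dip, hf) {
      ifelse(dip,
             ifelse(d == 1L, ifelse(hf, 0L, 2L), 1L),  # flip one allele
             2L - d)                                    # hemizygous flip
    }
    dos[err] <- flip(dos, diploid, half)[err]
  }
  if (p$n_misgenotyped > 0) {
    bad <- sample(which(!par), p$n_misgenotyped)
    for (b in bad) {
      hit <- which(male)[runif(sum(male)) < 0.08]
      if (length(hit) == 0) hit <- which(male)[1]
      dos[b, hit] <- 1L
    }
    misgeno <- core$map$snp_id[sort(bad)]
  } else {
    misgeno <- character(0)
  }
  if (p$missing_rate > 0) {
    dos[matrix(runif(length(dos)) < p$missing_rate, nrow = nrow(dos))] <- NA_integer_
  }
  storage.mode(dos) <- "integer"
  list(calls = dos, clean_dosage = clean, misgenotyped_snps = misgeno)
}

## Clean phased haplotypes: two rows per female, one per male (his X).
phased_from_core <- function(core) {
  male <- core$samples$sex == "male"
  rows <- list()
  meta <- list()
  for (i in seq_len(nrow(core$samples))) {
    s <- core$samples[i, ]
    rows[[length(rows) + 1]] <- core$hap1[i, ]
    meta[[length(meta) + 1]] <- data.frame(
      sample_id = s$sample_id, copy = 1L, sex = s$sex,
      population = s$population, species = s$species, stringsAsFactors = FALSE)
    if (!male[i]) {
      rows[[length(rows) + 1]] <- core$hap2[i, ]
      meta[[length(meta) + 1]] <- data.frame(
        sample_id = s$sample_id, copy = 2L, sex = s$sex,
        population = s$population, species = s$species, stringsAsFactors = FALSE)
    }
  }
  phased_haplotypes(do.call(rbind, rows), core$pos, do.call(rbind, meta),
                    snp_id = core$map$snp_id, coding = "allele_b")
}

assemble_dataset <- function(core) {
  fin <- finalize_genotypes(core)
  gm <- genotype_matrix(core$map, core$samples, fin$calls)
  truth <- structure(list(
    params = core$params, seed = core$seed,
    founders = core$founders, founder_freqs = core$founder_freqs,
    nearest_root = core$nearest_root,
    hap1 = core$hap1, hap2 = core$hap2, paths = core$paths,
    clean_dosage = fin$clean_dosage,
    par_boundary_bp = core$par_boundary_bp,
    par_snps = core$params$par_snps,
    misgenotyped_snps = fin$misgenotyped_snps,
    sweeps = core$sweeps, core = core), class = "sim_truth")
  list(gm = gm, haps = phased_from_core(core), truth = truth)
}

#' Simulate a neutral X-chromosome dataset
#'
#' Founder-mosaic model: an all-ancestral root haplotype, `n_founders`
#' founders mutated independently per SNP from the root, outgroup haplotypes
#' drawn from the founders nearest the root, and each focal haplotype a
#' founder mosaic with switch probability `recomb_rate` per SNP boundary.
#' Females carry two haplotypes; males one outside the PAR and two inside.
#' Missingness and symmetric genotyping error are applied last. Fully
#' reproducible from `seed`.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return list with `gm` (a [genotype_matrix()]), `haps` (clean
#'   [phased_haplotypes()]: two rows per female, one per male) and `truth`
#'   (a `sim_truth` holding founders, mosaic paths, clean dosages, the PAR
#'   boundary and any sweep spans).
#' @export
simulate_neutral <- function(params = sim_params(), seed = 1) {
  core <- simulate_core(params, seed)
  if (!is.null(params$sweeps)) {
    core <- apply_sweeps(core, params$sweeps, seed)
  }
  assemble_dataset(core)
}

#' Inject a hard sweep into a simulated dataset
#'
#' Within each span, every focal haplotype is independently replaced by the
#' swept haplotype with probability `f_s`. `origin = "ancestral"` sweeps the
#' founder nearest the root; `origin = "derived"` sweeps a novel haplotype
#' at least 5 mutations from every founder within the span. Haplotypes
#' outside the span are untouched; noise (error/missingness) is re-applied
#' from the dataset's own seed, so un-swept cells are unchanged.
#'
#' @param dataset output of [simulate_neutral()].
#' @param truth the matching `sim_truth` (defaults to `dataset$truth`).
#' @param sweep_spec data.frame with `snp_start`, `snp_end` (SNP indices,
#'   outside the PAR), `f_s`, `origin` (`"ancestral"`/`"derived"`).
#' @return list with modified `gm`, `haps`, `truth`.
#' @export
inject_sweep <- function(dataset, truth = dataset$truth, sweep_spec) {
  p <- truth$params
  if (any(sweep_spec$snp_start <= truth$par_snps)) {
    stop("sweep span overlaps the PAR")
  }
  if (any(sweep_spec$snp_end > p$n_snps)) stop("sweep span beyond the map")
  core <- truth$core
  core <- apply_sweeps(core, sweep_spec, truth$seed)
  assemble_dataset(core)
}

#' Simulate a dataset carrying one hard sweep
#'
#' Convenience preset: [simulate_neutral()] plus one sweep of `span_snps`
#' SNPs centred in the hemizygous region.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @param f_s sweep haplotype frequency (default 0.9).
#' @param span_snps sweep span in SNPs (default 70).
#' @param origin `"ancestral"` or `"derived"`.
#' @return As [simulate_neutral()]; the span is recorded in
#'   `truth$sweeps`.
#' @export
simulate_sweep <- function(params = sim_params(), seed = 1, f_s = 0.9,
                           span_snps = 70, origin = "derived") {
  p <- params
  mid <- p$par_snps + floor((p$n_snps - p$par_snps) / 2)
  start <- mid - floor(span_snps / 2)
  spec <- data.frame(snp_start = start, snp_end = start + span_snps - 1,
                     f_s = f_s, origin = origin, stringsAsFactors = FALSE)
  ds <- simulate_neutral(p, seed)
  inject_sweep(ds, ds$truth, spec)
}

#' Write a simulated dataset to disk
#'
#' Emits a phased VCF, a PLINK bed/bim/fam trio, a sample sheet TSV and a
#' truth JSON under one prefix.
#'
#' @param dataset output of [simulate_neutral()] or [simulate_sweep()].
#' @param prefix output path prefix.
#' @return Paths written, invisibly.
#' @export
write_sim_dataset <- function(dataset, prefix) {
  write_genotypes(dataset$gm, prefix, format = "plink-bed")
  vcf <- paste0(prefix, ".vcf")
  write_vcf_raw(dataset$gm, vcf)
  sheet <- paste0(prefix, "_samples.tsv")
  write_tsv(dataset$gm$samples, sheet)
  tr <- dataset$truth
  js <- paste0(prefix, "_truth.json")
  jsonlite::write_json(list(
    seed = tr$seed, par_boundary_bp = tr$par_boundary_bp,
    par_snps = tr$par_snps,
    n_founders = tr$params$n_founders,
    misgenotyped_snps = tr$misgenotyped_snps,
    sweeps = lapply(tr$sweeps, function(s) s[c("snp_start", "snp_end",
                                               "start_bp", "end_bp",
                                               "f_s", "origin")])),
    js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(prefix, vcf, sheet, js))
}
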