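## Independent brute-force oracles and small fixture builders. These
## deliberately avoid the package's internal algorithms: pairwise loops and
## exhaustive enumeration only.

## Minimal genotype_matrix builder from a dosage matrix (SNPs x samples).
toy_gm <- function(calls, sex = NULL, species = NULL, pos = NULL,
                   in_par = NULL, population = NULL) {
  n_snp <- nrow(calls)
  n_samp <- ncol(calls)
  if (is.null(sex)) sex <- rep("female", n_samp)
  if (is.null(species)) species <- rep("focal", n_samp)
  if (is.null(population)) population <- rep("breedA", n_samp)
  if (is.null(pos)) pos <- seq_len(n_snp) * 10000L
  map <- data.frame(snp_id = paste0("s", seq_len(n_snp)), chrom = "X",
                    pos_bp = pos, allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)
  if (!is.null(in_par)) map$in_par <- in_par
  samples <- data.frame(sample_id = paste0("ind", seq_len(n_samp)),
                        sex = sex, population = population, species = species,
                        stringsAsFactors = FALSE)
  genotype_matrix(map, samples, calls)
}

toy_haps <- function(H, pos = NULL, sex = NULL, species = NULL,
                     population = NULL, coding = "ancestral") {
  n <- nrow(H)
  if (is.null(pos)) pos <- seq_len(ncol(H)) * 10000L
  if (is.null(sex)) sex <- rep("male", n)
  if (is.null(species)) species <- rep("focal", n)
  if (is.null(population)) population <- rep("breedA", n)
  phased_haplotypes(H, pos,
                    data.frame(sample_id = paste0("h", seq_len(n)), copy = 1L,
                               sex = sex, population = population,
                               species = species, stringsAsFactors = FALSE),
                    coding = coding)
}

## Oracle: effective number of haplotypes by direct formula on frequencies.
oracle_nh <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (k in seq_along(counts)) acc <- acc + (counts[k] / total)^2
  1 / acc
}

## Oracle: all maximal admissible runs by exhaustive segment enumeration.
## Returns qualifying segments (start index, end index) for one genotype
## vector under one allowance set plus the global run constraints.
oracle_roh <- function(g, pos, max_gap, max_het, max_missing,
                       min_snps = 15, min_len = 250000, density = 20000,
                       class_lo = 0, class_hi = Inf) {
  n <- length(g)
  admissible <- function(i, j) {
    if (j < i) return(FALSE)
    if (j > i && any(diff(pos[i:j]) > max_gap)) return(FALSE)
    seg <- g[i:j]
    sum(seg == 1L, na.rm = TRUE) <= max_het && sum(is.na(seg)) <= max_missing
  }
  out <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!admissible(i, j)) next
      ## maximal: no admissible extension on either side
      if (i > 1 && admissible(i - 1, j)) next
      if (j < n && admissible(i, j + 1)) next
      len <- pos[j] - pos[i]
      nsnp <- j - i + 1
      if (nsnp < min_snps || len < min_len) next
      if (len / nsnp > density) next
      if (len < class_lo || len >= class_hi) next
      out <- rbind(out, c(i, j))
    }
  }
  out
}

## Oracle: EHH decay by explicit pairwise comparison. Same curve convention
## as the package definition: the first point below the cutoff is retained.
oracle_ehh_curve <- function(H, pos, core, allele, direction, cutoff = 0.05) {
  carriers <- which(H[, core] == allele)
  if (length(carriers) < 2) return(NULL)
  pr <- combn(carriers, 2)
  idx <- if (direction == "right") core:ncol(H) else core:1
  ehh <- numeric(0)
  keep_pos <- integer(0)
  for (k in seq_along(idx)) {
    span <- if (direction == "right") core:idx[k] else idx[k]:core
    same <- 0
    for (c2 in seq_len(ncol(pr))) {
      if (all(H[pr[1, c2], span] == H[pr[2, c2], span])) same <- same + 1
    }
    e <- same / ncol(pr)
    ehh <- c(ehh, e)
    keep_pos <- c(keep_pos, pos[idx[k]])
    if (e < cutoff || e == 0) break
  }
  data.frame(pos_bp = keep_pos, ehh = ehh)
}

oracle_trapezoid <- function(curve) {
  if (is.null(curve) || nrow(curve) < 2) return(0)
  acc <- 0
  for (k in 2:nrow(curve)) {
    acc <- acc + abs(curve$pos_bp[k] - curve$pos_bp[k - 1]) *
      (curve$ehh[k] + curve$ehh[k - 1]) / 2
  }
  acc
}

## Oracle: raw iHS at one core SNP by pairwise EHH curves + trapezoids.
oracle_ihs <- function(H, pos, core, cutoff = 0.05) {
  ihh_side <- function(allele) {
    l <- oracle_trapezoid(oracle_ehh_curve(H, pos, core, allele, "left", cutoff))
    r <- oracle_trapezoid(oracle_ehh_curve(H, pos, core, allele, "right", cutoff))
    l + r
  }
  a <- ihh_side(0L)
  d <- ihh_side(1L)
  if (a == 0 || d == 0) return(NA_real_)
  log(a / d)
}

## Oracle: raw nSL at one core SNP by explicit pairwise tract lengths.
oracle_nsl <- function(H, core) {
  sl <- function(allele) {
    carriers <- which(H[, core] == allele)
    if (length(carriers) < 2) return(NA_real_)
    pr <- combn(carriers, 2)
    tracts <- numeric(ncol(pr))
    for (c2 in seq_len(ncol(pr))) {
      a <- H[pr[1, c2], ]
      b <- H[pr[2, c2], ]
      len <- 1
      j <- core + 1
      while (j <= ncol(H) && a[j] == b[j]) { len <- len + 1; j <- j + 1 }
      j <- core - 1
      while (j >= 1 && a[j] == b[j]) { len <- len + 1; j <- j - 1 }
      tracts[c2] <- len
    }
    mean(tracts)
  }
  a <- sl(0L)
  d <- sl(1L)
  if (is.na(a) || is.na(d)) return(NA_real_)
  log(a / d)
}

## Oracle: minimum spanning network by exhaustive Kruskal-with-ties.
oracle_msn <- function(H) {
  n <- nrow(H)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) d[i, j] <- sum(H[i, ] != H[j, ])
  comp <- seq_len(n)
  edges <- NULL
  for (w in sort(unique(d[upper.tri(d)]))) {
    snap <- comp
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d[i, j] == w && snap[i] != snap[j]) {
        edges <- rbind(edges, c(i, j, w))
        comp[comp == comp[j]] <- comp[i]
      }
    }
    if (length(unique(comp)) == 1) break
  }
  edges
}
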