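test_that("call_roh honours the run constraints on hand-built vectors", {
  ## 14 consecutive homozygous SNPs: below min_snps, no ROH
  g <- c(rep(0L, 14), 1L, rep(0L, 5))
  pos <- cumsum(rep(20000L, 20))
  gm <- toy_gm(matrix(g, ncol = 1), pos = pos)
  expect_equal(nrow(call_roh(gm)), 0L)

  ## 20 homozygous SNPs spanning ~300 kb with ~16 kb gaps: one ROH, class 0.25-1 Mb
  pos2 <- as.integer(seq(1e6, 1.3e6, length.out = 20))
  gm2 <- toy_gm(matrix(rep(2L, 20), ncol = 1), pos = pos2)
  segs <- call_roh(gm2)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 20L)
  expect_equal(segs$length_class, "0.25-1Mb")
  expect_equal(segs$start_bp, pos2[1])
  expect_equal(segs$end_bp, pos2[20])

  ## same 20 SNPs over only 200 kb: below the minimum length
  pos3 <- as.integer(seq(1e6, 1.2e6, length.out = 20))
  gm3 <- toy_gm(matrix(rep(2L, 20), ncol = 1), pos = pos3)
  expect_equal(nrow(call_roh(gm3)), 0L)

  ## a heterozygote splits a strict-class run
  g4 <- rep(0L, 41); g4[21] <- 1L
  pos4 <- as.integer(seq(1e6, 1.42e6, length.out = 41))  # ~10.5 kb gaps
  gm4 <- toy_gm(matrix(g4, ncol = 1), pos = pos4)
  segs4 <- call_roh(gm4)
  ## two flanking 20-SNP runs, each ~200 kb: too short, so nothing in class 1;
  ## wider-allowance classes admit the het but the 0.42 Mb run is below their
  ## length ranges
  expect_equal(nrow(segs4), 0L)

  expect_error(call_roh(toy_gm(matrix(0L, 5, 1), sex = "male")), "female")
})

test_that("call_roh agrees with the exhaustive segment-enumeration oracle", {
  set.seed(101)
  params <- roh_params()
  n_rep <- 30
  for (rep_i in seq_len(n_rep)) {
    n <- sample(60:120, 1)
    pos <- as.integer(cumsum(sample(c(5000:30000, 300000), n, replace = TRUE,
                                    prob = c(rep(1, 25001), 40))))
    g <- sample(c(0L, 0L, 2L, 2L, 1L, NA_integer_), n, replace = TRUE,
                prob = c(8, 8, 8, 8, 1, 0.5))
    gm <- toy_gm(matrix(g, ncol = 1), pos = pos)
    mine <- call_roh(gm, params)
    expected <- NULL
    for (ci in seq_len(nrow(params$classes))) {
      o <- oracle_roh(g, pos, params$max_gap_bp,
                      params$classes$max_het[ci],
                      params$classes$max_missing[ci],
                      min_snps = params$min_snps,
                      min_len = params$min_len_bp,
                      density = params$min_density_bp_per_snp,
                      class_lo = params$classes$lo_bp[ci],
                      class_hi = params$classes$hi_bp[ci])
      if (!is.null(o)) {
        expected <- rbind(expected,
                          data.frame(start_bp = pos[o[, 1]],
                                     end_bp = pos[o[, 2]]))
      }
    }
    got <- mine[, c("start_bp", "end_bp")]
    if (is.null(expected)) {
      expect_equal(nrow(got), 0L)
    } else {
      o1 <- expected[order(expected$start_bp, expected$end_bp), ]
      o2 <- got[order(got$start_bp, got$end_bp), ]
      expect_equal(unname(as.matrix(o2)), unname(as.matrix(o1)))
    }
  }
})

test_that("per-SNP ROH frequency counts each female once", {
  map <- data.frame(snp_id = paste0("s", 1:10), chrom = "X",
                    pos_bp = seq(1e5, 1e6, length.out = 10),
                    allele_a = "A", allele_b = "B")
  ## no segments
  empty <- call_roh(toy_gm(matrix(1L, 10, 1),
                           pos = as.integer(seq(1e5, 1e6, length.out = 10))))
  f0 <- snp_roh_frequency(empty, map, 5)
  expect_true(all(f0$frequency == 0))
  ## overlapping runs from one female count once; a second female adds one
  segs <- data.frame(sample_id = c("f1", "f1", "f2"),
                     start_bp = c(1e5, 2e5, 1e5),
                     end_bp = c(5e5, 7e5, 3e5))
  f <- snp_roh_frequency(segs, map, 101)
  covered_both <- map$pos_bp <= 3e5
  expect_equal(max(f$count), 2L)
  expect_true(all(f$count[covered_both] == 2L))
  ## the headline frequency: 40 covering females out of 101
  segs40 <- data.frame(sample_id = paste0("f", 1:40),
                       start_bp = 1e5, end_bp = 1e6)
  f40 <- snp_roh_frequency(segs40, map, 101)
  expect_equal(round(f40$frequency[1], 3), 0.396)
})

test_that("ROH -log10(P) transform follows the upper normal tail", {
  freqs <- data.frame(snp_id = paste0("s", 1:5), pos_bp = 1:5 * 1e5,
                      count = c(1, 2, 3, 4, 5), frequency = c(.1, .2, .3, .4, .5))
  out <- roh_neglogp(freqs)
  ## f = mean -> z = 0 -> p = 0.5
  expect_equal(out$neglogp[3], -log10(0.5), tolerance = 1e-10)
  ## monotone in frequency
  expect_true(all(diff(out$neglogp) > 0))
  ## transform matches the closed form on an arbitrary profile
  f2 <- data.frame(snp_id = 1:40, pos_bp = 1:40,
                   frequency = 0.2 + 0.05 * scale(seq_len(40))[, 1])
  out2 <- roh_neglogp(f2)
  z <- (f2$frequency - mean(f2$frequency)) / sd(f2$frequency)
  expect_equal(out2$neglogp, -log10(pnorm(z, lower.tail = FALSE)),
               tolerance = 1e-12)
  expect_equal(-log10(pnorm(2, lower.tail = FALSE)), 1.6430, tolerance = 1e-4)
  expect_error(roh_neglogp(data.frame(frequency = rep(0.3, 5))), "variance")
})

test_that("simpleM reduces to 1 for a single SNP and halves for duplicated panels", {
  gm1 <- toy_gm(matrix(c(0L, 1L, 2L, 1L, 0L), 1, 5))
  sm1 <- simple_m(gm1)
  expect_equal(sm1$m_eff, 1L)
  expect_equal(sm1$threshold_neglogp, -log10(0.05), tolerance = 1e-12)

  set.seed(55)
  M <- 40; n <- 400
  x <- matrix(rbinom(M * n, 2, 0.5), nrow = M)
  sm_ind <- simple_m(x)
  expect_lte(abs(sm_ind$m_eff - M) / M, 0.05)
  sm_dup <- simple_m(rbind(x, x))
  expect_lte(abs(sm_dup$m_eff - M) / M, 0.05)
})

test_that("eROHi signals are maximal consecutive outlier runs ranked by peak", {
  base <- data.frame(snp_id = paste0("s", 1:20), pos_bp = 1:20 * 1e5,
                     neglogp = rep(1, 20))
  expect_equal(nrow(call_erohi_signals(base, threshold = 3.3)), 0L)
  ## one 5-SNP outlier run
  pro <- base
  pro$neglogp[6:10] <- c(3.5, 4.0, 8.0, 3.4, 3.3)
  sig <- call_erohi_signals(pro, threshold = 3.3)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$n_outlier_snps, 5L)
  expect_equal(sig$start_bp, pro$pos_bp[6])
  expect_equal(sig$end_bp, pro$pos_bp[10])
  expect_equal(sig$peak_neglogp, 8.0)
  ## a sub-threshold SNP splits two runs; ranking by peak
  pro2 <- base
  pro2$neglogp[3:4] <- 5
  pro2$neglogp[5] <- 1
  pro2$neglogp[6:7] <- c(9, 3.4)
  sig2 <- call_erohi_signals(pro2, threshold = 3.3)
  expect_equal(nrow(sig2), 2L)
  expect_equal(sig2$peak_neglogp, c(9, 5))
  ## a singleton outlier is not a signal at min_consecutive = 2
  pro3 <- base
  pro3$neglogp[12] <- 10
  expect_equal(nrow(call_erohi_signals(pro3, threshold = 3.3)), 0L)
})

test_that("ROH coverage conserves the per-segment SNP totals", {
  ds <- simulate_neutral(sim_params(n_snps = 400, par_snps = 40, n_males = 5,
                                    n_females = 25, n_outgroup_males = 1,
                                    n_outgroup_females = 1,
                                    recomb_rate = 0.005, n_founders = 4),
                         seed = 77)
  gm <- clean_hemizygous(ds$gm, ds$truth$par_boundary_bp)
  fem <- gm$samples$sex == "female"
  gm$samples <- gm$samples[fem, , drop = FALSE]
  gm$calls <- gm$calls[, fem, drop = FALSE]
  segs <- call_roh(gm)
  freqs <- snp_roh_frequency(segs, gm$map, sum(fem))
  ## union coverage is bounded by summed per-segment coverage and both agree
  ## when one run per female per region
  per_female_cov <- sapply(unique(segs$sample_id), function(id) {
    s <- segs[segs$sample_id == id, ]
    covered <- rep(FALSE, nrow(gm$map))
    for (r in seq_len(nrow(s))) {
      covered <- covered | (gm$map$pos_bp >= s$start_bp[r] &
                              gm$map$pos_bp <= s$end_bp[r])
    }
    sum(covered)
  })
  expect_equal(sum(freqs$count), sum(per_female_cov))
})

test_that("the top eROHi signal localizes an engineered autozygosity hotspot", {
  hits <- 0
  n_rep <- 5
  for (s in seq_len(n_rep)) {
    sw <- simulate_sweep(seed = 700 + s, f_s = 0.9)
    gm <- clean_hemizygous(sw$gm, detect_par(sw$gm)$par_boundary_bp)
    fem <- gm$samples$sex == "female" & gm$samples$species == "focal"
    gmf <- gm
    gmf$samples <- gm$samples[fem, , drop = FALSE]
    gmf$calls <- gm$calls[, fem, drop = FALSE]
    segs <- call_roh(gmf)
    fr <- roh_neglogp(snp_roh_frequency(segs, gm$map, sum(fem)))
    sig <- call_erohi_signals(fr, threshold = 3.3)
    sp <- sw$truth$sweeps[[1]]
    if (nrow(sig) > 0 &&
        sig$start_bp[1] <= sp$end_bp && sig$end_bp[1] >= sp$start_bp) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, n_rep - 1)
})
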