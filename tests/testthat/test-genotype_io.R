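test_that("PLINK and VCF round-trips preserve the genotype matrix", {
  ds <- simulate_neutral(sim_params(n_snps = 50, par_snps = 10, n_males = 4,
                                    n_females = 4, n_outgroup_males = 1,
                                    n_outgroup_females = 1), seed = 11)
  gm <- ds$gm
  pref <- file.path(tempdir(), "rt")
  write_genotypes(gm, pref, format = "plink-bed")
  back <- read_genotypes(pref, "plink-bed", gm$samples)
  expect_identical(unname(back$calls), unname(gm$calls))
  expect_equal(back$map$pos_bp, gm$map$pos_bp)
  expect_equal(back$samples$sample_id, gm$samples$sample_id)

  vcf <- file.path(tempdir(), "rt.vcf")
  write_genotypes(gm, vcf, format = "vcf")
  back2 <- read_genotypes(vcf, "vcf", gm$samples)
  expect_identical(unname(back2$calls), unname(gm$calls))
})

test_that("generated PLINK fixture matches the generator's truth table", {
  ds <- simulate_neutral(sim_params(n_snps = 50, par_snps = 10, n_males = 5,
                                    n_females = 5, n_outgroup_males = 1,
                                    n_outgroup_females = 1,
                                    missing_rate = 0, error_rate = 0),
                         seed = 3)
  pref <- file.path(tempdir(), "truthtab")
  write_genotypes(ds$gm, pref, format = "plink-bed")
  back <- read_genotypes(pref, "plink-bed", ds$gm$samples)
  expect_identical(unname(back$calls), unname(ds$truth$clean_dosage))
})

test_that("a ./. VCF call yields exactly one missing cell; tiny identity round-trip", {
  vcf <- file.path(tempdir(), "mini.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
               "X\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/1\t./."), vcf)
  sheet <- data.frame(sample_id = c("a", "b"), sex = "female",
                      population = "p", species = "focal")
  gm <- read_genotypes(vcf, "vcf", sheet)
  expect_equal(sum(is.na(gm$calls)), 1L)
  expect_equal(unname(gm$calls[1, 1]), 1L)
  ## write-then-read identity
  out <- file.path(tempdir(), "mini2.vcf")
  write_genotypes(gm, out, format = "vcf")
  gm2 <- read_genotypes(out, "vcf", sheet)
  expect_identical(gm2$calls, gm$calls)
})

test_that("unknown sample ids and non-biallelic records are handled", {
  vcf <- file.path(tempdir(), "multi.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta",
               "X\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0",
               "X\t200\tsnp2\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), vcf)
  sheet <- data.frame(sample_id = "a", sex = "female", population = "p",
                      species = "focal")
  expect_warning(gm <- read_genotypes(vcf, "vcf", sheet), "non-biallelic")
  expect_equal(nrow(gm$map), 1L)
  bad_sheet <- data.frame(sample_id = "zz", sex = "female", population = "p",
                          species = "focal")
  expect_error(suppressWarnings(read_genotypes(vcf, "vcf", bad_sheet)),
               "absent")
})

test_that("observed heterozygosity counts dosage-1 calls over non-missing", {
  calls <- rbind(rep(1L, 10),                      # all het
                 rep(c(0L, 2L), 5),                 # no het
                 c(rep(1L, 3), rep(0L, 7)),         # 3 of 10
                 rep(NA_integer_, 10))              # undefined
  gm <- toy_gm(calls)
  hp <- observed_heterozygosity(gm, "female")
  expect_equal(hp$h_obs[1], 1.0)
  expect_equal(hp$h_obs[2], 0.0)
  expect_equal(hp$h_obs[3], 0.3)
  expect_true(is.na(hp$h_obs[4]))
  expect_equal(hp$n_called[4], 0L)
  expect_error(observed_heterozygosity(gm, "male"), "no samples")
})

test_that("detect_par recovers a sharp diploid-to-hemizygous transition", {
  set.seed(42)
  n_snp <- 400; n_male <- 20
  calls <- matrix(0L, n_snp, n_male)
  ## first 100 SNPs diploid with H_O ~ 0.3-0.5
  for (i in 1:100) calls[i, ] <- sample(0:2, n_male, replace = TRUE,
                                        prob = c(0.35, 0.4, 0.25))
  for (i in 101:n_snp) calls[i, ] <- sample(c(0L, 2L), n_male, replace = TRUE)
  gm <- toy_gm(calls, sex = rep("male", n_male))
  pd <- detect_par(gm)
  expect_equal(pd$par_boundary_bp, gm$map$pos_bp[100])
  expect_equal(pd$n_par_snps, 100L)
  expect_length(pd$mis_genotyped_snp_ids, 0)
})

test_that("detect_par flags isolated hemizygous heterozygous SNPs as mis-genotyped", {
  ds <- simulate_neutral(sim_params(n_misgenotyped = 4), seed = 5)
  pd <- detect_par(ds$gm)
  expect_equal(pd$par_boundary_bp, ds$truth$par_boundary_bp)
  expect_true(all(ds$truth$misgenotyped_snps %in% pd$mis_genotyped_snp_ids))
})

test_that("detect_par on all-hemizygous males warns and places no PAR", {
  set.seed(7)
  calls <- matrix(sample(c(0L, 2L), 200 * 12, replace = TRUE), 200, 12)
  gm <- toy_gm(calls, sex = rep("male", 12))
  expect_warning(pd <- detect_par(gm), "no PAR")
  expect_equal(pd$par_boundary_bp, 0L)
  expect_length(pd$mis_genotyped_snp_ids, 0)
})

test_that("clean_hemizygous leaves no male heterozygous non-PAR calls", {
  ds <- simulate_neutral(sim_params(n_misgenotyped = 6), seed = 9)
  pd <- detect_par(ds$gm)
  gm <- clean_hemizygous(ds$gm, pd$par_boundary_bp)
  male <- gm$samples$sex == "male"
  hemi <- !gm$map$in_par
  expect_equal(sum(gm$calls[hemi, male] == 1L, na.rm = TRUE), 0L)
  rep <- attr(gm, "cleaning_report")
  expect_true(all(ds$truth$misgenotyped_snps %in% rep$mis_genotyped_dropped))
})

test_that("qc_filter drops low-call-rate SNPs and respects strict HWE exclusion", {
  set.seed(13)
  calls <- matrix(sample(0:2, 10 * 20, replace = TRUE), 10, 20)
  calls[3, 1:4] <- NA  # 80% call rate
  calls[7, 1:3] <- NA  # 85% call rate
  gm <- toy_gm(calls)
  out <- suppressMessages(qc_filter(gm, snp_call_rate = 0.90))
  expect_equal(nrow(out$map), 8L)
  expect_setequal(attr(out, "qc_report")$id[attr(out, "qc_report")$type == "snp"],
                  c("s3", "s7"))

  ## HWE boundary: p == hwe_p is retained (strict <)
  hwe_calls <- matrix(rep(c(0L, 2L), each = 10), nrow = 1)  # no hets, p small
  gm2 <- toy_gm(hwe_calls)
  p_exact <- xselscan:::hwe_midp(10, 0, 10)
  kept <- suppressMessages(qc_filter(gm2, hwe_p = p_exact))
  expect_equal(nrow(kept$map), 1L)
  w <- testthat::capture_warnings(
    dropped <- suppressMessages(qc_filter(gm2, hwe_p = p_exact * 1.01)))
  expect_true(any(grepl("removed every SNP", w)))
  expect_equal(nrow(dropped$map), 0L)
})

test_that("qc_filter uses quality scores when present and is idempotent", {
  ds <- simulate_neutral(sim_params(n_snps = 300, par_snps = 30, n_males = 20,
                                    n_females = 20, n_outgroup_males = 2,
                                    n_outgroup_females = 2), seed = 21)
  gm <- ds$gm
  gm$map$gentrain <- 1; gm$map$gencall <- 1
  gm$map$gentrain[5] <- 0.2   # below 0.4
  gm$map$gencall[9] <- 0.8    # <= 0.8 drops
  once <- qc_filter(gm)
  expect_false(any(once$map$snp_id %in% gm$map$snp_id[c(5, 9)]))
  twice <- qc_filter(once)
  expect_identical(unname(twice$calls), unname(once$calls))
  expect_identical(twice$map$snp_id, once$map$snp_id)
})

test_that("hwe mid-p exact test matches a chi-square sanity ordering", {
  ## strong heterozygote deficit gives a much smaller p than equilibrium
  p_bad <- xselscan:::hwe_midp(50, 0, 50)
  p_ok <- xselscan:::hwe_midp(25, 50, 25)
  expect_lt(p_bad, 1e-7)
  expect_gt(p_ok, 0.05)
})

test_that("ancestral assignment takes the outgroup majority allele copy count", {
  ## monomorphic outgroup
  calls <- matrix(c(0L, 0L, 0L), 1, 3)
  gm <- toy_gm(calls, species = rep("outgroup", 3))
  expect_equal(assign_ancestral(gm)$ancestral, "a")
  ## dosages {0,0,0,2,2}: allele a copies 6 vs b copies 4
  gm2 <- toy_gm(matrix(c(0L, 0L, 0L, 2L, 2L), 1, 5),
                species = rep("outgroup", 5))
  expect_equal(assign_ancestral(gm2)$ancestral, "a")
  ## exact tie
  gm3 <- toy_gm(matrix(c(0L, 2L), 1, 2), species = rep("outgroup", 2))
  expect_equal(assign_ancestral(gm3)$ancestral, "unknown")
  ## no outgroup at all
  gm4 <- toy_gm(matrix(0L, 1, 2))
  expect_error(assign_ancestral(gm4), "outgroup")
})

test_that("ancestral recoding flips allele-b-ancestral columns and is an involution", {
  set.seed(31)
  H <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12)
  hp <- toy_haps(H, coding = "allele_b")
  map <- data.frame(snp_id = paste0("s", 1:12), chrom = "X",
                    pos_bp = hp$pos_bp, allele_a = "A", allele_b = "B",
                    ancestral = rep(c("a", "b", "unknown"), 4))
  rec <- recode_ancestral(hp, map)
  expect_equal(rec$coding, "ancestral")
  flip <- map$ancestral == "b"
  expect_identical(rec$haps[, flip], 1L - H[, flip])
  expect_identical(rec$haps[, !flip], H[, !flip])
  expect_equal(attr(rec, "unknown_ancestral"), which(map$ancestral == "unknown"))
  back <- recode_ancestral(rec, map)
  expect_identical(back$haps, H)
  ## ancestral = a everywhere is the identity
  map$ancestral <- "a"
  expect_identical(recode_ancestral(hp, map)$haps, H)
})
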