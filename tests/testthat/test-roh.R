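test_that("minimum SNP count follows the chance-run equation and its monotonicity", {
  expect_identical(min_snp_count(1, 1, 0.95, 0.05), 1L)
  # frozen from a high-precision evaluation of ln(0.05/7.8e6)/ln(0.7) = 52.89
  expect_identical(min_snp_count(40000, 195, 0.30, 0.05), 53L)
  expect_error(min_snp_count(100, 10, 0), "\\(0, 1\\)")
  expect_error(min_snp_count(100, 10, 1), "\\(0, 1\\)")

  # non-increasing in het, non-decreasing in ns*ni
  hets <- seq(0.05, 0.95, by = 0.05)
  Ls <- vapply(hets, function(h) min_snp_count(5000, 100, h), integer(1))
  expect_true(all(diff(Ls) <= 0))
  sizes <- c(10, 100, 1000, 10000)
  Ln <- vapply(sizes, function(s) min_snp_count(s, 10, 0.3), integer(1))
  expect_true(all(diff(Ln) >= 0))
})

test_that("window flags tolerate one het per window and score truncated chromosomes", {
  pos <- seq(1e5, by = 2e4, length.out = 200)
  all_hom <- rep(0L, 200)
  expect_true(all(window_homozygosity_flags(all_hom, pos)))

  one_het <- all_hom
  one_het[100] <- 1L
  expect_true(all(window_homozygosity_flags(one_het, pos)))

  # two hets 5 SNPs apart: windows spanning both fail, but every SNP is
  # still covered by a window holding at most one of them (hand
  # enumeration: for SNP i some window in [i-49, i] ends before SNP 105 or
  # starts after SNP 100), so nothing is unflagged
  two_het <- all_hom
  two_het[c(100, 105)] <- 1L
  expect_true(all(window_homozygosity_flags(two_het, pos)))

  # a SNP bracketed by two hets on each side within window reach has no
  # passing window left: hets at 98,99 and 101,102 unflag SNP 100 only
  # (98 and 102 keep the windows ending/starting at them, which hold a
  # single het; 99-101 always co-occur with two hets)
  quad <- all_hom
  quad[c(98, 99, 101, 102)] <- 1L
  fl <- window_homozygosity_flags(quad, pos)
  expect_equal(which(!fl), 99:101)

  # short chromosome: single truncated window
  expect_true(all(window_homozygosity_flags(rep(0L, 10), pos[1:10])))
  expect_false(any(window_homozygosity_flags(c(rep(0L, 8), 1L, 1L), pos[1:10])))

  expect_error(window_homozygosity_flags(all_hom, rev(pos)), "increasing")
})

test_that("call_roh splits on gaps and enforces length, count and density", {
  params <- roh_params()
  # flagged stretch spanning only 0.5 Mb is rejected by minimum length
  pos <- seq(1e5, by = 1e4, length.out = 51)
  seg <- call_roh(rep(TRUE, 51), pos, params, L = 10)
  expect_equal(nrow(seg), 0L)

  # 2 Mb stretch passes and reports its SNP extent
  pos2 <- seq(1e6, by = 2e4, length.out = 101)
  seg2 <- call_roh(rep(TRUE, 101), pos2, params, L = 50)
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$start, 1e6)
  expect_equal(seg2$end, 3e6)
  expect_equal(seg2$n_snps, 101L)

  # a > 1 Mb gap splits the run; halves fail the length filter
  pos3 <- c(seq(1e6, by = 2e4, length.out = 30),
            seq(4e6, by = 2e4, length.out = 30))
  seg3 <- call_roh(rep(TRUE, 60), pos3, params, L = 10)
  expect_equal(nrow(seg3), 0L)

  # sparse SNPs violate the density bound
  pos4 <- seq(1e6, by = 2e5, length.out = 11)  # 1 SNP / 200 kb
  seg4 <- call_roh(rep(TRUE, 11), pos4, params, L = 5)
  expect_equal(nrow(seg4), 0L)

  # empty input and all-unflagged input give empty output
  expect_equal(nrow(call_roh(logical(0), numeric(0), params, 1)), 0L)
  expect_equal(nrow(call_roh(rep(FALSE, 10), pos[1:10], params, 1)), 0L)
})

test_that("segment invariants hold on fuzzed inputs", {
  params <- roh_params()
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(60:400, 1)
    pos <- sort(sample.int(8e6, n))
    flags <- runif(n) < 0.8
    L <- sample(5:30, 1)
    segs <- call_roh(flags, pos, params, L)
    if (nrow(segs)) {
      expect_true(all(segs$length_bp >= params$min_len_bp))
      expect_true(all(segs$n_snps >= L))
      expect_true(all(segs$length_bp / segs$n_snps <=
                        params$min_density_bp_per_snp))
      expect_true(all(segs$length_bp == segs$end - segs$start + 1))
    }
  }
})

test_that("planted homozygous tracts are recovered end to end; clean samples stay empty", {
  cfg <- sim_config(n_breeds = 1, samples_per_breed = 3, n_sites = 600,
                    chrom_lengths = c("1" = 12e6), F = 0.05,
                    missing_rate = 0, seed = 101)
  gm <- simulate_genotypes(simulate_frequencies(cfg))
  gm <- plant_roh(gm, "breed1_01", "1", 4e6, 6.5e6, seed = 202)
  truth <- attr(gm, "planted_tracts")

  segs <- detect_roh(gm)
  s1 <- segs[segs$sample_id == "breed1_01", ]
  expect_equal(nrow(s1), 1L)
  # the called segment covers the tract's SNP extent
  expect_lte(s1$start, truth$first_snp)
  expect_gte(s1$end, truth$last_snp)
  # no calls in the untouched samples (heterozygous background)
  expect_equal(nrow(segs[segs$sample_id != "breed1_01", ]), 0L)

  # an all-heterozygous sample yields nothing
  het_gm <- gm
  het_gm$calls[2, ] <- 1L
  segs2 <- detect_roh(het_gm)
  expect_equal(nrow(segs2[segs2$sample_id == "breed1_02", ]), 0L)
})

test_that("plant_roh leaves no hets inside and does not touch the outside", {
  gm <- sim_two_breeds(seed = 77, n_sites = 500, samples_per_breed = 5)
  before <- gm$calls
  gm2 <- plant_roh(gm, "breed1_01", "1", 1e6, 2e7, seed = 3)
  idx <- which(gm2$sites$chrom == "1" & gm2$sites$pos >= 1e6 &
                 gm2$sites$pos <= 2e7)
  inside <- gm2$calls[1, idx]
  expect_false(any(inside == 1L, na.rm = TRUE))
  outside <- setdiff(seq_len(n_sites(gm2)), idx)
  expect_identical(gm2$calls[1, outside], before[1, outside])
  expect_identical(gm2$calls[-1, ], before[-1, ])
  expect_error(plant_roh(gm, "breed1_01", "1", 1, 10, seed = 1), "2 sites")
})

test_that("ROH summaries aggregate counts, lengths and coverage with zeros kept", {
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        breed = c("x", "x", "y"))
  segs <- data.frame(
    sample_id = c("a", "a", "c"), breed = c("x", "x", "y"),
    chrom = "1", start = c(1e6, 5e6, 2e6), end = c(2.5e6, 7.5e6, 4e6),
    n_snps = c(60L, 100L, 80L),
    length_bp = c(1.5e6, 2.5e6, 2e6)
  )
  s <- roh_summary(segs, samples, autosome_len = 1e8)
  expect_equal(s$per_sample$n_roh, c(2L, 0L, 1L))
  expect_equal(s$per_sample$total_bp[1], 4e6)
  expect_equal(s$per_sample$mean_bp[1], 2e6)
  expect_equal(s$per_sample$coverage[1], 0.04)
  expect_equal(s$per_sample$coverage[2], 0)
  expect_equal(s$per_breed$mean_n_roh[s$per_breed$breed == "x"], 1)
})

test_that("per-SNP incidence counts covering individuals inclusively", {
  sites <- data.frame(chrom = "1", pos = (1:30) * 1e5)
  segs <- data.frame(sample_id = c("a", "b"), chrom = "1",
                     start = c(10e5, 15e5), end = c(20e5, 25e5))
  inc <- snp_incidence(segs, sites, n_individuals = 4)
  expect_equal(inc$incidence[sites$pos < 10e5], rep(0, 9))
  expect_equal(inc$incidence[sites$pos == 10e5], 0.25)   # inclusive start
  expect_equal(inc$incidence[sites$pos == 17e5], 0.5)    # overlap of both
  expect_equal(inc$incidence[sites$pos == 25e5], 0.25)   # inclusive end
  expect_equal(inc$incidence[sites$pos > 25e5], rep(0, 5))
  expect_true(all(inc$incidence >= 0 & inc$incidence <= 1))

  # no segments -> all zeros
  inc0 <- snp_incidence(segs[0, ], sites, 4)
  expect_equal(inc0$incidence, rep(0, 30))
})

test_that("island calling uses the strict top-quantile rule with a 2-SNP minimum", {
  pos <- seq(1e5, by = 1e4, length.out = 1000)
  # constructed spike: 10 consecutive SNPs far above the 99th percentile
  inc <- data.frame(chrom = "1", pos = pos,
                    incidence = c(rep(0.1, 700), rep(0.9, 10), rep(0.1, 290)))
  res <- island_call(inc)
  expect_equal(nrow(res$islands), 1L)
  expect_equal(res$islands$start, pos[701])
  expect_equal(res$islands$end, pos[710])
  expect_equal(res$islands$n_snps, 10L)
  expect_equal(res$islands$peak_incidence, 0.9)

  # uniform incidence: nothing strictly above the threshold
  flat <- data.frame(chrom = "1", pos = pos, incidence = rep(0.3, 1000))
  res2 <- island_call(flat)
  expect_equal(res2$threshold, 0.3)
  expect_equal(nrow(res2$islands), 0L)

  # a single spiking SNP is not an island
  single <- flat
  single$incidence[500] <- 0.95
  expect_equal(nrow(island_call(single)$islands), 0L)

  expect_warning(island_call(inc[1:50, ]), "100 SNPs")
})

test_that("interval annotation reports overlaps inclusively and skips bad rows", {
  feats <- data.frame(chrom = c("1", "1", "1", "2"),
                      start = c(400L, 501L, 2000L, 100L),
                      end = c(900L, 900L, 3000L, 200L),
                      name = c("gA", "gB", "gC", "gD"))
  isl <- data.frame(chrom = c("1", "1"), start = c(100L, 1500L),
                    end = c(500L, 2500L))
  ann <- annotate_intervals(isl, feats)
  expect_equal(ann$genes, c("gA", "gC"))   # [100,500] vs [501,900]: adjacency, no overlap
  expect_equal(ann$n_genes, c(1L, 1L))

  bad <- rbind(feats, data.frame(chrom = "1", start = 10L, end = 5L,
                                 name = "broken"))
  expect_warning(ann2 <- annotate_intervals(isl, bad), "malformed")
  expect_equal(ann2$genes, ann$genes)

  # GFF input restricted to gene features
  gff <- tempfile(fileext = ".gff3")
  write_toy_gff(gff)
  ann3 <- annotate_intervals(data.frame(chrom = "1", start = 9000L,
                                        end = 30000L), gff)
  expect_equal(ann3$genes, "g1")
})
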