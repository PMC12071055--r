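test_that("priority assignment follows the category tiers and dedups by priority", {
  cand <- data.frame(
    chrom = "1",
    pos = c(100L, 200L, 300L, 300L, 400L, 500L),
    category = c("breed_specific", "common", "common", "trait_related",
                 "wgs_polymorphic", "wgs_polymorphic"),
    maf = c(NA, NA, NA, NA, 0.3, 0.1)
  )
  expect_warning(ap <- assign_priorities(cand), "MAF <= 0.2")
  expect_equal(attr(ap, "n_rejected_wgs_maf"), 1L)
  expect_equal(nrow(ap), 4L)  # one duplicate collapsed, one wgs rejected
  expect_equal(ap$priority[ap$pos == 100], 1L)   # breed_specific
  expect_equal(ap$priority[ap$pos == 200], 2L)   # common
  expect_equal(ap$priority[ap$pos == 400], 3L)   # wgs_polymorphic
  # duplicated physical site keeps the trait_related (tier 1) entry
  expect_equal(ap$category[ap$pos == 300], "trait_related")
  expect_error(assign_priorities(data.frame(chrom = "1", pos = 1L,
                                            category = "mystery")),
               "unknown candidate category")
})

test_that("window tiling covers chromosomes disjointly with a short last window", {
  w <- make_windows(c(a = 150000, b = 120000, c = 49999), width = 50000)
  expect_equal(sum(w$chrom == "a"), 3L)
  expect_equal(sum(w$chrom == "b"), 3L)
  expect_equal(sum(w$chrom == "c"), 1L)
  wb <- w[w$chrom == "b", ]
  expect_equal(wb$end[3] - wb$start[3], 20000)
  # tiling: starts chain onto ends, covering [0, length)
  expect_equal(wb$start, c(0, 50000, 100000))
  expect_equal(w$end[w$chrom == "c"], 49999)
  expect_error(make_windows(c(a = 1e5), width = 0), "positive")
})

test_that("sd2_spacing equals the variance of the four positions", {
  expect_equal(sd2_spacing(0, 100, 25, 75), 1562.5)
  expect_equal(sd2_spacing(0, 50000, 10000, 40000), 425e6)
  # oracle: population variance of {S, Ni, Nj, E}
  set.seed(1)
  for (i in 1:50) {
    e <- sample(1000:100000, 1)
    ps <- sort(sample.int(e - 1, 2))
    x <- c(0, ps, e)
    expect_equal(sd2_spacing(0, e, ps[1], ps[2]),
                 mean((x - mean(x))^2))
  }
  expect_error(sd2_spacing(0, 100, 50, 50), "ni < nj")
  expect_error(sd2_spacing(0, 100, 10, 200), "within")
})

test_that("per-window selection applies the keep/pair/fill/empty rules", {
  w <- list(chrom = "1", start = 0, end = 50000)
  one <- data.frame(chrom = "1", pos = 30000L, priority = 1L)
  r1 <- select_window_sites(w, one)
  expect_equal(r1$rule, "kept_single")
  expect_equal(r1$selected$pos, 30000L)

  # three candidates: {10000,25000} ties {25000,40000}; leftmost pair wins
  three <- data.frame(chrom = "1", pos = c(10000L, 25000L, 40000L),
                      priority = 1L)
  r2 <- select_window_sites(w, three)
  expect_equal(r2$rule, "sd2_pair")
  expect_equal(r2$selected$pos, c(10000L, 25000L))
  expect_equal(r2$sd2, 354687500)

  # empty window: highest priority from the pool, then MAF
  pool <- data.frame(chrom = "1", pos = c(1000L, 2000L, 3000L),
                     priority = c(3L, 3L, 2L), maf = c(0.4, 0.1, 0.3))
  r3 <- select_window_sites(w, three[0, ], pool)
  expect_equal(r3$rule, "filled")
  expect_equal(r3$selected$pos, 3000L)   # the only priority-2 site
  pool2 <- pool[pool$priority == 3L, ]
  r4 <- select_window_sites(w, three[0, ], pool2)
  expect_equal(r4$selected$pos, 1000L)   # higher MAF wins within a tier

  r5 <- select_window_sites(w, three[0, ])
  expect_equal(r5$rule, "empty")
  expect_equal(nrow(r5$selected), 0L)
})

test_that("pair choice equals exhaustive brute force on crowded windows", {
  # independent oracle: direct minimisation of the 4-point variance
  brute <- function(s, e, pos) {
    best <- NULL; best_v <- Inf
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
      if (pos[i] >= pos[j]) next
      x <- c(s, pos[i], pos[j], e)
      v <- mean((x - mean(x))^2)
      if (v < best_v - 1e-9) { best_v <- v; best <- c(pos[i], pos[j]) }
    }
    list(pair = best, v = best_v)
  }
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(3:15, 1)
    pos <- sort(sample(seq(1, 50000), n))
    cand <- data.frame(chrom = "1", pos = pos, priority = 1L)
    res <- select_window_sites(list(chrom = "1", start = 0, end = 50000), cand)
    expect_equal(res$sd2, brute(0, 50000, pos)$v, tolerance = 1e-9)
  }
})

test_that("build_panel conserves input sites, caps windows at two, audits rules", {
  set.seed(5)
  lens <- c("1" = 2e6, "2" = 1e6)   # 60 windows
  n <- 150
  cand <- data.frame(
    chrom = sample(names(lens), n, replace = TRUE, prob = c(2, 1)),
    pos = NA_integer_,
    category = sample(c("breed_specific", "common"), n, replace = TRUE)
  )
  cand$pos <- as.integer(ceiling(runif(n) * lens[cand$chrom]))
  cand <- cand[!duplicated(paste(cand$chrom, cand$pos)), ]
  ap <- assign_priorities(cand)
  panel <- build_panel(ap, lens)

  sel <- panel$selected
  # conservation: every selected site is an input candidate, selected once
  expect_true(all(paste(sel$chrom, sel$pos) %in% paste(ap$chrom, ap$pos)))
  expect_false(anyDuplicated(paste(sel$chrom, sel$pos)) > 0)
  # literal mode: at most two sites per window
  expect_lte(max(table(sel$window_id)), 2L)
  # audit covers every window and is consistent with selection counts
  expect_equal(nrow(panel$audit), sum(ceiling(lens / 50000)))
  expect_equal(sum(panel$audit$rule == "kept_single"),
               sum(sel$rule == "kept_single"))

  # determinism: identical inputs give identical panels
  panel2 <- build_panel(ap, lens)
  expect_identical(panel$selected, panel2$selected)

  # unknown chromosome is a named error
  bad <- ap
  bad$chrom[1] <- "zz"
  expect_error(build_panel(bad, lens), "zz")
})

test_that("four disjoint category lists placed two-per-window are all retained", {
  sizes <- c(breed_specific = 40, trait_related = 30, common = 20,
             wgs_polymorphic = 10)
  total <- sum(sizes)
  n_win <- ceiling(total / 2)
  width <- 50000
  lens <- c("1" = n_win * width)
  slot <- seq_len(total)
  win <- (slot - 1) %/% 2
  off <- ifelse(slot %% 2 == 1, 10000L, 40000L)
  cand <- data.frame(
    chrom = "1", pos = as.integer(win * width + off),
    category = rep(names(sizes), sizes),
    maf = 0.3
  )
  panel <- build_panel(assign_priorities(cand), lens, width = width)
  expect_equal(nrow(panel$selected), total)
  expect_equal(as.integer(panel$counts[names(sizes)]), unname(sizes))
})

test_that("empty windows are filled from the supplement pool one site each", {
  lens <- c("1" = 200000)  # 4 windows
  cand <- data.frame(chrom = "1", pos = c(30000L, 60000L),
                     category = "common")
  sup <- data.frame(chrom = "1",
                    pos = c(110000L, 120000L, 160000L),
                    priority = 3L, maf = c(0.1, 0.45, 0.2))
  panel <- build_panel(assign_priorities(cand), lens, supplement = sup)
  sel <- panel$selected
  expect_equal(nrow(sel), 4L)
  expect_equal(sel$pos[sel$rule == "filled"], c(120000L, 160000L))
  expect_equal(sort(panel$audit$rule),
               sort(c("kept_single", "kept_single", "filled", "filled")))
})

test_that("panel report aggregates chromosome counts, MAF bins and occupancy", {
  lens <- c("1" = 150000, "2" = 100000)
  cand <- data.frame(chrom = c("1", "1", "2"),
                     pos = c(20000L, 70000L, 30000L),
                     category = "common", maf = c(0.25, 0.25, 0.07))
  panel <- build_panel(assign_priorities(cand), lens)
  rep <- panel_report(panel)
  expect_equal(rep$n_sites, 3L)
  expect_equal(as.integer(rep$chrom_counts), c(2L, 1L))
  expect_equal(sum(rep$maf_hist), 3)
  expect_equal(as.integer(rep$maf_hist[["[0.20,0.30)"]]), 2L)
  expect_equal(as.integer(rep$maf_hist[["[0.05,0.10)"]]), 1L)
})

test_that("detection rate reproduces a printed percentage from its counts", {
  expect_equal(round(panel_detection_rate(40477, 42686), 2), 94.83)
})

test_that("group QC comparison runs Welch tests pairwise and handles edge cases", {
  # identical groups -> p = 1
  v <- data.frame(sample_id = as.character(1:10), value = rep(0.99, 10))
  res <- qc_compare_groups(v, rep(c("a", "b"), each = 5))
  expect_equal(res$p_value, 1)

  # clearly separated groups -> tiny p
  set.seed(9)
  v2 <- data.frame(sample_id = as.character(1:40),
                   value = c(rnorm(20, 0.99, 1e-2), rnorm(20, 0.95, 1e-2)))
  res2 <- qc_compare_groups(v2, rep(c("f", "m"), each = 20))
  expect_lt(res2$p_value, 0.001)
  expect_true(res2$significant)

  # three groups -> three pairwise tests; tiny group excluded with warning
  g3 <- rep(c("a", "b", "c"), c(5, 5, 10))
  v3 <- data.frame(sample_id = as.character(1:20), value = rnorm(20))
  expect_equal(nrow(qc_compare_groups(v3, g3)), 3L)
  g4 <- rep(c("a", "b", "c"), c(1, 9, 10))
  expect_warning(res4 <- qc_compare_groups(v3, g4), "excluding")
  expect_equal(nrow(res4), 1L)
})

test_that("site region classification respects precedence and strand", {
  gff <- tempfile(fileext = ".gff3")
  write_toy_gff(gff)
  sites <- data.frame(
    chrom = "1",
    pos = c(11000L,  # inside g1 exon 1        -> exonic
            15000L,  # inside g1, between exons -> intronic
            8000L,   # 2 kb before g1 (+)       -> upstream
            22000L,  # 2 kb after g1 (+)        -> downstream
            62000L,  # 2 kb past g2 end, g2 is - strand -> upstream
            48000L,  # 2 kb before g2 start (- strand)  -> downstream
            500000L) # far from everything      -> intergenic
  )
  expect_equal(classify_site_region(sites, gff),
               c("exonic", "intronic", "upstream", "downstream",
                 "upstream", "downstream", "intergenic"))

  # unknown chromosome falls back to intergenic with a warning
  expect_warning(
    lab <- classify_site_region(data.frame(chrom = "9", pos = 100L), gff),
    "absent")
  expect_equal(lab, "intergenic")
})
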