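# Fixtures shared across tests; everything is built in code.

# tiny hand-checkable genotype matrix: 4 samples (2 breeds) x 5 sites
toy_gm <- function() {
  calls <- rbind(
    s1 = c(0L, 0L, 2L, 1L, 0L),
    s2 = c(0L, 1L, 2L, NA, 0L),
    s3 = c(0L, 2L, 0L, 1L, NA),
    s4 = c(0L, NA, 0L, 2L, 0L)
  )
  geno_matrix(
    calls,
    data.frame(chrom = c("1", "1", "1", "2", "2"),
               pos = c(100L, 5000L, 9000L, 150L, 700L),
               site_id = paste0("s", 1:5),
               ref = "A", alt = "G"),
    data.frame(sample_id = paste0("s", 1:4),
               breed = c("x", "x", "y", "y"),
               sex = c("M", "F", "M", "F"))
  )
}

# write a small handcrafted VCF (3 samples x 5 records + 1 triallelic)
write_toy_vcf <- function(path, sample_table_path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##contig=<ID=2>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", "C", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0|1", "1|1", "./.", sep = "\t"),
    paste("1", "300", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
          "1/2", "0/0", "0/1", sep = "\t"),   # triallelic: skipped
    paste("1", "400", "rs4", "T", "C", ".", "PASS", ".", "GT",
          "0/.", "0/0", "0/0", sep = "\t"),   # half-missing call
    paste("2", "150", "rs5", "A", "C", ".", "PASS", ".", "GT",
          "1/1", "0/1", "0/0", sep = "\t"),
    paste("2", "900", "rs6", "G", "C", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/1", sep = "\t")
  )
  writeLines(lines, path)
  writeLines(c("sample_id\tbreed\tsex",
               "A\tlocal\tM", "B\tlocal\tF", "C\tforeign\tM"),
             sample_table_path)
  invisible(path)
}

# simulated two-breed matrix reused by several tests
sim_two_breeds <- function(seed = 11, F = 0.2, n_sites = 1500,
                           samples_per_breed = 30, missing_rate = 0) {
  cfg <- sim_config(n_breeds = 2, samples_per_breed = samples_per_breed,
                    n_sites = n_sites, chrom_lengths = c("1" = 3e7, "2" = 3e7),
                    F = F, missing_rate = missing_rate, seed = seed)
  simulate_genotypes(simulate_frequencies(cfg))
}

# GFF3 fixture: two genes on chrom 1 (one per strand), exon structure on g1
write_toy_gff <- function(path) {
  lines <- c(
    "##gff-version 3",
    paste("1", "test", "gene", "10000", "20000", ".", "+", ".",
          "ID=g1;Name=g1", sep = "\t"),
    paste("1", "test", "exon", "10000", "12000", ".", "+", ".",
          "ID=g1e1;Parent=g1", sep = "\t"),
    paste("1", "test", "exon", "18000", "20000", ".", "+", ".",
          "ID=g1e2;Parent=g1", sep = "\t"),
    paste("1", "test", "gene", "50000", "60000", ".", "-", ".",
          "ID=g2;Name=g2", sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
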