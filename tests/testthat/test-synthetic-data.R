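test_that("repeat library generation is deterministic and validated", {
  sp <- repeat_family_spec("famA", monomer_length = 500L)
  lib <- make_repeat_library(list(sp), seed = 7)
  expect_equal(nrow(lib), 1L)
  expect_equal(nchar(lib$sequence), 500L)

  lib2 <- make_repeat_library(list(sp), seed = 7)
  expect_identical(lib, lib2)

  specs <- list(repeat_family_spec("a"), repeat_family_spec("b"),
                repeat_family_spec("c", "tandem", monomer_length = 180L))
  lib3 <- make_repeat_library(specs, seed = 1)
  expect_equal(lib3$name, c("a", "b", "c"))
  expect_equal(lib3$class_label, c("other", "other", "tandem"))

  expect_error(make_repeat_library(list(repeat_family_spec("x"),
                                        repeat_family_spec("x")), 1),
               "duplicate")
  expect_error(repeat_family_spec("y", monomer_length = 10), "monomer_length")
  expect_error(repeat_family_spec("y", intra_family_divergence = 0.5),
               "divergence")
})

test_that("family copies follow the substitution-only model", {
  monomer <- rand_dna(500, seed = 11)
  expect_identical(evolve_family_copies(monomer, 5, 0, seed = 1),
                   rep(monomer, 5))

  copies <- evolve_family_copies(monomer, 200, 0.1, seed = 1)
  expect_true(all(nchar(copies) == 500))
  # oracle: direct mismatch count; per-site retention 0.9, so the mean
  # per-copy identity is binomial(500, 0.9)/500 averaged over 200 copies
  tmpl <- strsplit(monomer, "")[[1]]
  ident <- vapply(copies, function(cp)
    mean(strsplit(cp, "")[[1]] == tmpl), numeric(1))
  se <- sqrt(0.9 * 0.1 / 500 / 200)
  expect_lt(abs(mean(ident) - 0.9), 3 * se)

  expect_identical(evolve_family_copies(monomer, 0, 0.1, 1), character(0))
  expect_identical(evolve_family_copies(monomer, 10, 0.05, 3),
                   evolve_family_copies(monomer, 10, 0.05, 3))
})

test_that("build_genome records a consistent truth table", {
  lib <- make_repeat_library(demo_specs(), seed = 2)
  g <- build_genome(lib, chrom_lengths = c(chr1 = 300000L, chr2 = 200000L),
                    seed = 5)
  expect_s3_class(g$truth, "data.frame")
  expect_true(all(g$truth$end > g$truth$start))
  for (ch in names(g$chromosomes)) {
    L <- nchar(g$chromosomes[[ch]])
    t_ch <- g$truth[g$truth$chrom == ch, ]
    expect_true(all(t_ch$end <= L))
    g_ch <- g$genes[g$genes$chrom == ch, ]
    expect_true(all(g_ch$end <= L))
  }
  # truth conservation: planted length per family = copies x monomer exactly
  # (substitution-only placement, no overlaps)
  lens <- tapply(g$truth$end - g$truth$start, g$truth$family, sum)
  expect_equal(as.vector(lens[c("GypsyA", "CopiaB", "TandemC")]),
               c(150 * 500, 120 * 450, 350 * 180))
  # planted sequence really is at the recorded coordinates
  i <- which(g$truth$family == "GypsyA")[1]
  placed <- substr(g$chromosomes[[g$truth$chrom[i]]],
                   g$truth$start[i] + 1, g$truth$end[i])
  monomer <- lib$sequence[lib$name == "GypsyA"]
  if (g$truth$strand[i] == "-") placed <- revcomp(placed)
  ident <- mean(strsplit(placed, "")[[1]] == strsplit(monomer, "")[[1]])
  expect_gt(ident, 0.85)  # divergence 0.05 from the ancestral monomer
})

test_that("placement bias orders gene density at insertion sites", {
  lib <- make_repeat_library(
    list(repeat_family_spec("neg", monomer_length = 500L,
                            target_copy_number = 120L, placement_bias = -1),
         repeat_family_spec("pos", monomer_length = 500L,
                            target_copy_number = 120L, placement_bias = 1)),
    seed = 3)
  g <- build_genome(lib, chrom_lengths = c(chr1 = 500000L), seed = 9)
  dn <- density_at(g$truth[g$truth$family == "neg", ], g$genes)
  dp <- density_at(g$truth[g$truth$family == "pos", ], g$genes)
  expect_lt(mean(dn), mean(dp))
})

test_that("tandem families form one contiguous block", {
  lib <- make_repeat_library(
    list(repeat_family_spec("tand", "tandem", monomer_length = 180L,
                            target_copy_number = 300L)), seed = 4)
  g <- build_genome(lib, chrom_lengths = c(chr1 = 400000L), seed = 6)
  t <- g$truth[order(g$truth$start), ]
  expect_equal(nrow(t), 300L)
  expect_equal(length(unique(t$chrom)), 1L)
  # head-to-tail: each copy starts where the previous one ends
  expect_true(all(t$start[-1] == t$end[-nrow(t)]))
  expect_equal(max(t$end) - min(t$start), 300L * 180L)  # ~54 kb block
})

test_that("degenerate and over-filled genomes are handled", {
  lib <- make_repeat_library(list(repeat_family_spec("a")), seed = 1)
  g <- build_genome(lib, copy_plan = c(a = 0L)[0],
                    chrom_lengths = c(chr1 = 100000L), seed = 1)
  expect_equal(nrow(g$truth), 0L)
  expect_gt(nrow(g$genes), 0L)

  big <- make_repeat_library(
    list(repeat_family_spec("huge", monomer_length = 5000L,
                            target_copy_number = 100L)), seed = 1)
  expect_error(build_genome(big, chrom_lengths = c(chr1 = 100000L), seed = 1),
               "exceeds genome length")
})

test_that("simulate_population draws calibrated SNPs and copy numbers", {
  means <- stats::setNames(rep(50, 20), sprintf("fam%02d", 1:20))

  # F = 0: population frequencies coincide; oracle = direct per-population
  # major-allele frequency from the emitted calls
  pc0 <- population_config(n_individuals_per_pop = 60L, snp_count = 1000L,
                           snp_divergence = 0, heterozygosity_rate = 0,
                           seed = 21)
  pop0 <- simulate_population(means, pc0)
  is1 <- pop0$labels$population == pc0$pop_labels[1]
  fdiff <- vapply(seq_len(ncol(pop0$genotypes)), function(j) {
    ref <- substr(pop0$genotypes[1, j], 1, 1)
    mean(substr(pop0$genotypes[is1, j], 1, 1) == ref) -
      mean(substr(pop0$genotypes[!is1, j], 1, 1) == ref)
  }, numeric(1))
  expect_lt(abs(mean(fdiff)), 0.01)

  # planted 2x effect on one family
  eff <- stats::setNames(rep(1, 20), names(means)); eff["fam03"] <- 2
  pc2 <- population_config(n_individuals_per_pop = 40L, snp_count = 10L,
                           repeat_effect = eff, seed = 22)
  pop2 <- simulate_population(means, pc2)
  is1 <- pop2$labels$population == pc2$pop_labels[1]
  ratio <- mean(pop2$copy_number[!is1, "fam03"]) /
    mean(pop2$copy_number[is1, "fam03"])
  expect_lt(abs(ratio - 2), 0.25)  # Poisson(50/100), n = 40 per pop

  expect_error(population_config(repeat_effect = 0), "repeat_effect")
  expect_identical(simulate_population(means, pc2)$copy_number,
                   pop2$copy_number)
})

test_that("shotgun reads sample the genome uniformly with labels", {
  lib <- make_repeat_library(demo_specs(), seed = 2)
  g <- build_genome(lib, chrom_lengths = c(chr1 = 300000L, chr2 = 200000L),
                    seed = 5)
  reads <- shotgun_reads(g, 2000, 150, seed = 8, individual = "i9",
                         population = "NSS")
  expect_equal(nrow(reads), 2000L)
  expect_true(all(nchar(reads$sequence) == 150L))
  expect_true(all(reads$individual == "i9" & reads$population == "NSS"))

  # repeat-derived fraction matches the planted repeat fraction: with a
  # half-read overlap rule the number of start positions hitting a placement
  # of length len is exactly len, so E[fraction] = planted fraction
  frac_genome <- sum(g$truth$end - g$truth$start) / sum(nchar(g$chromosomes))
  fam <- true_read_family(reads, g, min_overlap = 75L)
  frac_reads <- mean(fam != "background")
  expect_lt(abs(frac_reads - frac_genome), 0.05)

  expect_identical(shotgun_reads(g, 50, 150, seed = 8),
                   shotgun_reads(g, 50, 150, seed = 8))
  expect_equal(nrow(shotgun_reads(g, 0, 150, seed = 1)), 0L)
  expect_error(shotgun_reads(c(chrA = rand_dna(100)), 10, 150, seed = 1),
               "exceeds shortest chromosome")
})

test_that("downsampling respects pair structure and exact counts", {
  lib <- make_repeat_library(demo_specs(), seed = 2)
  g <- build_genome(lib, chrom_lengths = c(chr1 = 500000L), seed = 5)
  paired <- shotgun_reads(g, 2000, 150, seed = 3, paired = TRUE)
  expect_equal(nrow(paired), 2000L)
  expect_equal(length(unique(paired$fragment_id)), 1000L)

  ds <- downsample_reads(paired, 600, seed = 4)
  expect_equal(nrow(ds), 600L)
  expect_false(anyDuplicated(ds$fragment_id) > 0)

  un <- shotgun_reads(g, 100, 150, seed = 6)
  same <- downsample_reads(un, 100, seed = 1)
  expect_setequal(same$read_id, un$read_id)
  expect_equal(nrow(downsample_reads(un, 0, seed = 1)), 0L)
  expect_error(downsample_reads(un, 101, seed = 1), "available")
  expect_error(downsample_reads(paired, 1001, seed = 1), "available")
})
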